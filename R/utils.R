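#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# seed argument makes them reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_cryomrf <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cryomrf_error")))
}

# Mutable binary min-heap keyed by (numeric key, character tiebreak).
# Used by the best-first top-K extraction; entries are arbitrary payloads.
heap_new <- function() {
  e <- new.env(parent = emptyenv())
  e$key <- numeric(0)
  e$tie <- character(0)
  e$val <- list()
  e
}

heap_size <- function(h) length(h$key)

heap_less <- function(h, i, j) {
  h$key[i] < h$key[j] || (h$key[i] == h$key[j] && h$tie[i] < h$tie[j])
}

heap_push <- function(h, key, tie, val) {
  n <- length(h$key) + 1L
  h$key[n] <- key
  h$tie[n] <- tie
  h$val[[n]] <- val
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(h, i, p)) {
      h$key[c(i, p)] <- h$key[c(p, i)]
      h$tie[c(i, p)] <- h$tie[c(p, i)]
      tmp <- h$val[[i]]; h$val[[i]] <- h$val[[p]]; h$val[[p]] <- tmp
      i <- p
    } else break
  }
  invisible(h)
}

heap_pop <- function(h) {
  n <- length(h$key)
  if (n == 0L) stop("pop from empty heap")
  out <- list(key = h$key[1L], tie = h$tie[1L], val = h$val[[1L]])
  h$key[1L] <- h$key[n]; h$tie[1L] <- h$tie[n]; h$val[[1L]] <- h$val[[n]]
  h$key <- h$key[-n]; h$tie <- h$tie[-n]; h$val[[n]] <- NULL
  n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= n && heap_less(h, l, m)) m <- l
    if (r <= n && heap_less(h, r, m)) m <- r
    if (m == i) break
    h$key[c(i, m)] <- h$key[c(m, i)]
    h$tie[c(i, m)] <- h$tie[c(m, i)]
    tmp <- h$val[[i]]; h$val[[i]] <- h$val[[m]]; h$val[[m]] <- tmp
    i <- m
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
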