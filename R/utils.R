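#' Round half away from zero
#'
#' Fixed-precision rounding used for all report tables: exact halves round
#' away from zero (so 0.125 -> 0.13), unlike base [round()]'s banker's
#' rounding. Internal computation keeps full precision; rounding is applied
#' only at the presentation layer.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13
#' round_half_up(0.1190, 2) # 0.12
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an epsilon proportional to x to undo binary representation
  # artifacts (e.g. 2.0785 stored as 2.07849999...)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(colocnet_error("colocnet_invalid_input", sprintf(...)))
}

stop_config <- function(...) {
  stop(colocnet_error("colocnet_config_error", sprintf(...)))
}

colocnet_error <- function(class, message) {
  structure(
    class = c(class, "colocnet_error", "error", "condition"),
    list(message = message, call = sys.call(-2))
  )
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_invalid("`%s` must be a single integer >= %d (got %s)",
                 name, min, paste(utils::head(x, 3), collapse = ","))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_config("`%s` must be a probability in [0, 1]", name)
  }
  as.numeric(x)
}

# Interval set helpers ------------------------------------------------------
# All intervals are half-open [start, end) integer-second matrices with
# columns start, end; rows sorted and disjoint ("canonical form").

iv_canon <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(matrix(numeric(0), 0, 2,
                                                 dimnames = list(NULL, c("start", "end"))))
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0L) return(iv_canon(NULL))
  m <- m[order(m[, 1]), , drop = FALSE]
  out_s <- numeric(nrow(m)); out_e <- numeric(nrow(m)); k <- 0L
  for (i in seq_len(nrow(m))) {
    if (k > 0L && m[i, 1] <= out_e[k]) {
      out_e[k] <- max(out_e[k], m[i, 2])
    } else {
      k <- k + 1L
      out_s[k] <- m[i, 1]; out_e[k] <- m[i, 2]
    }
  }
  cbind(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

iv_intersect <- function(a, b) {
  a <- iv_canon(a); b <- iv_canon(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_canon(NULL))
  res <- list(); k <- 0L
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b[j, 2] <= a[i, 1]) j <- j + 1L
    jj <- j
    while (jj <= nrow(b) && b[jj, 1] < a[i, 2]) {
      k <- k + 1L
      res[[k]] <- c(max(a[i, 1], b[jj, 1]), min(a[i, 2], b[jj, 2]))
      jj <- jj + 1L
    }
  }
  if (k == 0L) return(iv_canon(NULL))
  iv_canon(do.call(rbind, res))
}

iv_subtract <- function(a, b) {
  a <- iv_canon(a); b <- iv_canon(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  res <- list(); k <- 0L
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    cuts <- b[b[, 2] > s & b[, 1] < e, , drop = FALSE]
    cur <- s
    if (nrow(cuts) > 0L) {
      for (j in seq_len(nrow(cuts))) {
        if (cuts[j, 1] > cur) { k <- k + 1L; res[[k]] <- c(cur, cuts[j, 1]) }
        cur <- max(cur, cuts[j, 2])
      }
    }
    if (cur < e) { k <- k + 1L; res[[k]] <- c(cur, e) }
  }
  if (k == 0L) return(iv_canon(NULL))
  iv_canon(do.call(rbind, res))
}

# seconds-of-day window(s) [h1, h2) expanded over the day range covered by m
iv_clock_window <- function(m, hours, day0 = 0) {
  if (nrow(m) == 0L) return(iv_canon(NULL))
  lo <- floor(min(m[, 1]) / 86400) * 86400
  hi <- ceiling(max(m[, 2]) / 86400) * 86400
  days <- seq(lo, hi - 1, by = 86400)
  win <- cbind(start = days + hours[1] * 3600, end = days + hours[2] * 3600)
  iv_canon(win)
}
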