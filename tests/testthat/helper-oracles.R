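# Independent brute-force reference implementations used to cross-check
# the package's estimators. These are deliberately written from the
# definitions (explicit normal equations, exhaustive interpolation,
# literal greedy loop) and share no code with the implementations in R/.

# weighted least squares of y on x through the origin, weights w:
# minimise sum w (y - b x)^2  =>  b = (x' W y) / (x' W x)
oracle_ivw <- function(bx, by, sey) {
  w <- 1 / sey^2
  b <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - b * bx)^2)
  j <- length(bx)
  phi <- if (j >= 2) max(1, sqrt(q / (j - 1))) else 1
  list(beta = b, se_fixed = se_fixed, se_random = se_fixed * phi, q = q)
}

# weighted linear regression with intercept via the explicit 2x2 normal
# equations, after orienting all exposure effects positive
oracle_egger <- function(bx, by, sey) {
  s <- sign(bx); s[s == 0] <- 1
  x <- bx * s; y <- by * s
  w <- 1 / sey^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  a <- (swxx * swy - swx * swxy) / det      # intercept
  b <- (sw * swxy - swx * swy) / det        # slope
  j <- length(x)
  q <- sum(w * (y - a - b * x)^2)
  scale <- max(1, sqrt(q / (j - 2)))
  se_a <- sqrt(swxx / det) * scale
  se_b <- sqrt(sw / det) * scale
  list(intercept = a, slope = b, se_intercept = se_a, se_slope = se_b,
       q = q)
}

# exhaustive cumulative-weight interpolation: walk every segment of the
# ordered ratios and locate the 50% crossing of the weight function
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  ww <- w[ord] / sum(w)
  p <- numeric(length(b))
  acc <- 0
  for (i in seq_along(b)) {
    p[i] <- acc + ww[i] / 2
    acc <- acc + ww[i]
  }
  if (p[1] >= 0.5) return(b[1])
  n <- length(b)
  if (p[n] <= 0.5) return(b[n])
  for (i in seq_len(n - 1)) {
    if (p[i] <= 0.5 && 0.5 <= p[i + 1]) {
      return(b[i] + (b[i + 1] - b[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("no crossing found")
}

# literal restatement of the greedy clumping rule on a small instance:
# repeatedly promote the best remaining variant (p, then se, then id)
# and delete everything linked to it within the window
oracle_clump_ids <- function(df, r2mat, r2_threshold, window_bp) {
  remaining <- df
  kept <- character(0)
  while (nrow(remaining) > 0) {
    o <- order(remaining$pvalue, remaining$se, remaining$variant_id,
               method = "radix")
    idx <- remaining[o[1], ]
    kept <- c(kept, idx$variant_id)
    drop <- vapply(seq_len(nrow(remaining)), function(k) {
      r <- remaining[k, ]
      if (r$variant_id == idx$variant_id) return(TRUE)
      if (!identical(r$chromosome, idx$chromosome)) return(FALSE)
      if (abs(r$position - idx$position) > window_bp) return(FALSE)
      r2mat[idx$variant_id, r$variant_id] > r2_threshold
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}
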