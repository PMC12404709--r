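# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw their randomness from seeds derived by stable
#' hashing of the stage name, so any stage can be re-run in isolation and
#' reproduce its part of a full run.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 7919) %% 2147483646L + 1L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  as.numeric(x)
}

# Ordinary least squares of every row of `y` on `design`, with a two-sided
# t-test on one coefficient. Vectorised across rows via a single QR
# factorisation; this is the shared engine behind DMP and DEG calling.
#
# y: features x samples matrix; design: samples x p model matrix.
# Returns a tibble with estimate, t, p per row of y, for column `coef`.
fit_rowwise_lm <- function(y, design, coef) {
  stopifnot(ncol(y) == nrow(design))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    kept <- qr_d$pivot[seq_len(qr_d$rank)]
    bad <- setdiff(colnames(design), colnames(design)[kept])
    abort(paste0(
      "Design matrix is rank deficient; collinear columns: ",
      paste(bad, collapse = ", ")
    ))
  }
  j <- match(coef, colnames(design))
  if (is.na(j)) abort(sprintf("Coefficient '%s' not in design.", coef))
  coefs <- qr.coef(qr_d, t(y))                      # p x features
  resid <- t(y) - design %*% coefs                  # samples x features
  df <- nrow(design) - ncol(design)
  if (df < 1L) abort("No residual degrees of freedom.")
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_d))[order(qr_d$pivot), order(qr_d$pivot), drop = FALSE]
  se <- sqrt(sigma2 * xtx_inv[j, j])
  est <- coefs[j, ]
  tstat <- est / se
  tstat[se == 0] <- 0
  p <- 2 * pt(-abs(tstat), df = df)
  p[se == 0] <- 1
  tibble::tibble(estimate = unname(est), statistic = unname(tstat), p = unname(p))
}

# Build a model matrix for group + covariates from a samples tibble.
# Group is coded 0 = control, 1 = RT so effects read RT minus control.
group_design <- function(samples, covariates = NULL) {
  if (!all(samples$group %in% c("control", "RT"))) {
    abort("`group` must be 'control' or 'RT'.")
  }
  x <- cbind("(Intercept)" = 1, group = as.numeric(samples$group == "RT"))
  for (cv in covariates) {
    if (!cv %in% names(samples)) abort(sprintf("Covariate '%s' not found.", cv))
    v <- samples[[cv]]
    if (!is.numeric(v)) v <- as.numeric(as.factor(v)) - 1
    if (anyNA(v)) abort(sprintf("Covariate '%s' has missing values.", cv))
    x <- cbind(x, v)
    colnames(x)[ncol(x)] <- cv
  }
  x
}

# Depth-normalise a spot x gene count matrix to the median total, then log1p.
log_normalise <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) totals[totals == 0] <- 1
  target <- median(totals)
  f <- target / totals
  if (inherits(counts, "sparseMatrix")) {
    x <- Matrix::Diagonal(x = f) %*% counts
    x <- methods::as(x, "CsparseMatrix")
    dimnames(x) <- dimnames(counts)
    x@x <- log1p(x@x)
  } else {
    x <- log1p(counts * f)
  }
  x
}
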