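#' Multiple imputation under a multivariate normal model
#'
#' Data-augmentation (MCMC) imputation for an arbitrary missingness pattern:
#' starting from mean-filled data, the sampler alternates an I-step (draw
#' missing cells from the conditional normal given the observed cells and
#' the current mean/covariance) with a P-step (draw the mean and covariance
#' from their posterior under the Jeffreys prior given the completed data).
#' After `burn_in` iterations, one completed dataset is taken every `thin`
#' iterations until `m` are collected. Binary columns are imputed on the
#' latent normal scale and thresholded at 0.5. Observed cells are never
#' modified; the chain is deterministic given `seed`.
#'
#' @param data Data frame or matrix of (approximately) continuous variables
#'   with `NA` for missing cells.
#' @param m Number of imputations (>= 2 unless nothing is missing).
#' @param burn_in Burn-in iterations (default 200).
#' @param thin Iterations between retained imputations (default 100).
#' @param seed Integer seed.
#' @param binary_cols Names of 0/1 columns to threshold after imputation.
#' @return List of `m` completed data frames; each carries an `imputation`
#'   attribute with its index.
#' @export
mvn_impute <- function(data, m = 5, burn_in = 200, thin = 100, seed = 1L,
                       binary_cols = NULL) {
  x <- as.matrix(as.data.frame(data))
  if (!is.numeric(x)) stop("all variables must be numeric")
  p <- ncol(x)
  n <- nrow(x)
  if (p < 1L || n < 2L) stop("need at least 2 rows and 1 column")
  miss <- is.na(x)
  all_missing <- colnames(x)[colSums(miss) == n]
  if (length(all_missing) > 0L) {
    stop("variable(s) 100% missing: ", paste(all_missing, collapse = ", "))
  }
  if (!any(miss)) {
    return(lapply(seq_len(m), function(k) {
      out <- as.data.frame(data)
      attr(out, "imputation") <- k
      out
    }))
  }
  if (m < 2) stop("m must be >= 2")
  obs_var <- vapply(seq_len(p), function(j) stats::var(x[!miss[, j], j]),
                    numeric(1))
  if (any(obs_var %in% 0)) {
    stop("variable(s) constant among observed cells: ",
         paste(colnames(x)[obs_var %in% 0], collapse = ", "))
  }
  set.seed(seed)
  # initialize missing cells at column means
  xc <- x
  for (j in seq_len(p)) xc[miss[, j], j] <- mean(x[, j], na.rm = TRUE)
  patterns <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), patterns)
  groups <- groups[vapply(names(groups), function(g) grepl("1", g), logical(1))]
  draws <- vector("list", m)
  taken <- 0L
  iter <- 0L
  total <- burn_in + (m - 1L) * thin + 1L
  while (taken < m) {
    iter <- iter + 1L
    # P-step: (mu, Sigma) | completed data, Jeffreys prior
    xbar <- colMeans(xc)
    S <- crossprod(sweep(xc, 2L, xbar))
    # near-duplicate columns (e.g. a binary indicator repeated unchanged
    # across measurement years) make S singular; a small ridge keeps the
    # augmentation chain proper without visibly perturbing the draws
    Sinv <- tryCatch(solve(S), error = function(e) {
      solve(S + diag(1e-6 * mean(diag(S)), p))
    })
    W <- stats::rWishart(1L, df = n - 1L, Sigma = Sinv)[, , 1L]
    Sigma <- solve(W)
    Sigma <- (Sigma + t(Sigma)) / 2
    mu <- MASS::mvrnorm(1L, xbar, Sigma / n)
    # I-step: missing | observed, (mu, Sigma), by missingness pattern
    for (g in names(groups)) {
      midx <- which(strsplit(g, "")[[1]] == "1")
      oidx <- setdiff(seq_len(p), midx)
      rows <- groups[[g]]
      if (length(oidx) == 0L) {
        xc[rows, midx] <- MASS::mvrnorm(length(rows), mu, Sigma)
        next
      }
      Soo_inv <- solve(Sigma[oidx, oidx, drop = FALSE])
      B <- Sigma[midx, oidx, drop = FALSE] %*% Soo_inv
      cond_var <- Sigma[midx, midx, drop = FALSE] -
        B %*% Sigma[oidx, midx, drop = FALSE]
      cond_var <- (cond_var + t(cond_var)) / 2
      dev <- sweep(xc[rows, oidx, drop = FALSE], 2L, mu[oidx])
      cmean <- matrix(mu[midx], length(rows), length(midx), byrow = TRUE) +
        dev %*% t(B)
      noise <- MASS::mvrnorm(length(rows), rep(0, length(midx)), cond_var)
      xc[rows, midx] <- cmean + matrix(noise, nrow = length(rows))
    }
    if (iter >= burn_in && (iter - burn_in) %% thin == 0L) {
      taken <- taken + 1L
      out <- as.data.frame(xc)
      for (b in intersect(binary_cols, colnames(out))) {
        out[[b]] <- as.numeric(out[[b]] >= 0.5)
      }
      # observed cells byte-identical to the input
      out[!miss] <- as.data.frame(x)[!miss]
      attr(out, "imputation") <- taken
      draws[[taken]] <- out
    }
    if (iter > total + burn_in) break
  }
  draws
}

#' Enforce the HDL/total-cholesterol constraint
#'
#' An imputed HDL above total cholesterol is logically impossible; wherever
#' `hdl > chol` the HDL value is replaced by `chol - 0.1`. Values already
#' consistent are untouched.
#'
#' @param chol Total cholesterol, mmol/l.
#' @param hdl HDL cholesterol, mmol/l.
#' @return Repaired HDL vector.
#' @examples
#' repair_hdl(4.0, 4.5)  # 3.9
#' repair_hdl(5.0, 1.2)  # unchanged
#' @export
repair_hdl <- function(chol, hdl) {
  ifelse(!is.na(hdl) & !is.na(chol) & hdl > chol, chol - 0.1, hdl)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance. The confidence interval uses the
#' standard small-sample degrees of freedom
#' `(m - 1) * (1 + W / ((1 + 1/m) B))^2` (normal when B = 0).
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation (squared-SE) variances.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `variance`, `within`, `between`, `df`, `ci`.
#' @examples
#' rubins_pool(c(1, 2, 3), c(0, 0, 0))  # estimate 2, variance 4/3
#' @export
rubins_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules need m >= 2 imputations")
  stopifnot(length(variances) == m, all(variances >= 0))
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df)
       else stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = qbar, variance = total, within = W, between = B, df = df,
       ci = c(qbar - q * sqrt(total), qbar + q * sqrt(total)))
}

#' Multiply impute a cohort's measurement columns
#'
#' Applies [mvn_impute()] jointly to the cohort's imputable measurement
#' columns (weight, height and the year-indexed smoking, cholesterol, HDL,
#' systolic blood pressure and HbA1c measurements), thresholds the smoking
#' indicators, and repairs any imputed HDL above the same-year total
#' cholesterol.
#'
#' @param cohort Cohort data frame with `NA` holes.
#' @param m,burn_in,thin,seed Passed to [mvn_impute()].
#' @return List of `m` completed cohorts.
#' @export
impute_cohort <- function(cohort, m = 5, burn_in = 200, thin = 100, seed = 1L) {
  cols <- imputable_columns(cohort)
  if (length(cols) == 0L) stop("cohort has no imputable columns")
  binaries <- grep("^smoker_", cols, value = TRUE)
  imps <- mvn_impute(cohort[cols], m = m, burn_in = burn_in, thin = thin,
                     seed = seed, binary_cols = binaries)
  lapply(imps, function(imp) {
    done <- cohort
    done[cols] <- imp
    for (yr in c(0, 1, 5)) {
      ch <- paste0("chol_y", yr)
      hd <- paste0("hdl_y", yr)
      if (all(c(ch, hd) %in% names(done))) {
        done[[hd]] <- repair_hdl(done[[ch]], done[[hd]])
      }
    }
    attr(done, "imputation") <- attr(imp, "imputation")
    done
  })
}
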