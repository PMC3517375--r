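#' Prepare an analysis table from a raw trial table
#'
#' Converts the generator's (or an imported trial's) column layout into the
#' analysis layout used by costing, outcomes, imputation and bootstrapping:
#' EQ-5D health-state profiles are converted to tariff utilities
#' (`utility_base`, `utility_fu`), and the 5-level state columns are dropped.
#' Tables that already carry utilities pass through unchanged.
#'
#' @param data Trial tibble from [generate_trial()] or [read_trial()].
#' @param tariff An [`eq5d_tariff`][dolan_tariff].
#' @return A tibble with one row per participant and numeric/flag analysis
#'   columns only.
#' @export
prepare_analysis_data <- function(data, tariff = dolan_tariff()) {
  state_dims <- c("mo", "sc", "ua", "pd", "ad")
  for (tp in c("base", "fu")) {
    ucol <- paste0("utility_", tp)
    scols <- paste0(state_dims, "_", tp)
    if (!ucol %in% names(data)) {
      if (!all(scols %in% names(data))) {
        stop("data has neither ", ucol, " nor the EQ-5D state columns ",
             paste(scols, collapse = ", "), call. = FALSE)
      }
      data[[ucol]] <- eq5d_utility(as.matrix(data[scols]), tariff)
    }
    data <- data[setdiff(names(data), scols)]
  }
  # per-session uptake is already carried by the contact/admin hour columns;
  # the raw count is NA by design in the self-help arm
  data[setdiff(names(data), "uptake_sessions")]
}

# clamping bounds applied after imputation draws (logical variable ranges)
analysis_bounds <- function() {
  list(
    audit_base = c(0, 40), audit_fu = c(0, 40),
    qols_base = c(16, 112), qols_fu = c(16, 112),
    bsi_base = c(0, 4), bsi_fu = c(0, 4),
    drinks_week_base = c(0, Inf),
    drinks7_base = c(0, Inf), drinks7_fu = c(0, Inf),
    absent_hours_base = c(0, 112), absent_hours_fu = c(0, 112),
    present_hours_base = c(0, 112), present_hours_fu = c(0, 112),
    time_invested_hours = c(0, Inf),
    contact_hours = c(0, Inf), admin_hours = c(0, Inf),
    utility_base = c(-0.594, 1), utility_fu = c(-0.594, 1)
  )
}

# EM for the multivariate normal with arbitrary missingness patterns.
# X: numeric matrix with NAs. Returns mu, sigma, loglik trace, iterations.
em_mvnorm <- function(X, tol = 1e-6, maxit = 500, ridge = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0)) {
    stop("EM requires at least one observed value per variable", call. = FALSE)
  }
  X0 <- X
  mu <- colMeans(X, na.rm = TRUE)
  X0[!obs] <- matrix(mu, n, p, byrow = TRUE)[!obs]
  sigma <- stats::cov(X0)
  sigma <- sigma + diag(ridge * mean(diag(sigma)) + 1e-10, p)

  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_key)

  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (rows in pats) {
      o <- obs[rows[1L], ]
      m <- !o
      Xo <- X[rows, o, drop = FALSE]
      k <- sum(o)
      So <- sigma[o, o, drop = FALSE]
      cho <- chol(So)
      dev <- sweep(Xo, 2L, mu[o])
      z <- backsolve(cho, t(dev), transpose = TRUE)
      ll <- ll - 0.5 * (length(rows) * (k * log(2 * pi) +
                                          2 * sum(log(diag(cho)))) +
                          sum(z^2))
      if (!any(m)) {
        T1 <- T1 + colSums_ix(Xo, o, p)
        T2[o, o] <- T2[o, o] + crossprod(Xo)
        next
      }
      B <- sigma[m, o, drop = FALSE] %*% chol2inv(cho)
      cond_mean <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
        dev %*% t(B)
      C <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
      Xhat <- matrix(0, length(rows), p)
      Xhat[, o] <- Xo
      Xhat[, m] <- cond_mean
      T1 <- T1 + colSums(Xhat)
      T2 <- T2 + crossprod(Xhat)
      T2[m, m] <- T2[m, m] + length(rows) * C
    }
    mu <- T1 / n
    sigma <- T2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    sigma <- sigma + diag(ridge * mean(diag(sigma)) + 1e-10, p)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      return(list(mu = mu, sigma = sigma, loglik = trace, iterations = it,
                  converged = TRUE))
    }
    ll_old <- ll
  }
  cond <- structure(
    class = c("netcea_em_nonconvergence", "error", "condition"),
    list(message = sprintf(
      "EM did not converge in %d iterations (last log-likelihood change %.3g)",
      maxit, if (length(trace) > 1) diff(utils::tail(trace, 2)) else NA_real_),
      call = NULL, trace = trace)
  )
  stop(cond)
}

colSums_ix <- function(Xo, o, p) {
  out <- numeric(p)
  out[o] <- colSums(Xo)
  out
}

#' Multiply impute missing follow-up data (bootstrap-EM multivariate normal)
#'
#' Missing cells are imputed `m` times under a joint multivariate-normal model
#' over all numeric variables (no explicit covariate list): for each
#' imputation the rows are resampled with replacement, the EM algorithm fits
#' the mean vector and covariance matrix on the resample, and the original
#' dataset's missing cells are then drawn from their conditional normal
#' distribution given the row's observed values under those parameters.
#' Binary fields are imputed on the latent continuous scale and thresholded
#' at 0.5; bounded scores, hours and utilities are clamped to their logical
#' ranges after the draw. One master seed spawns per-imputation streams, so
#' `m` and `seed` jointly determine the output.
#'
#' @param data Analysis tibble (see [prepare_analysis_data()]); missingness
#'   must be confined to follow-up (`*_fu`) fields and every row needs at
#'   least one observed covariate.
#' @param m Number of imputations (>= 2; the trial analysis used 5).
#' @param seed Master integer seed.
#' @param tol Relative log-likelihood convergence tolerance of the EM.
#' @param maxit Maximum EM iterations; non-convergence raises a diagnostic
#'   error carrying the log-likelihood trace.
#' @param ridge Small ridge added to the covariance diagonal for numerical
#'   stability.
#' @return An object of class `imputation_set`: list with `datasets` (m
#'   completed tibbles, identical to the input on observed cells), `m`,
#'   `seed`, `missing_map` (tibble of imputed row/column cells) and
#'   `em_iterations`.
#' @export
impute_trial <- function(data, m = 5, seed = 1L, tol = 1e-6, maxit = 500,
                         ridge = 1e-4) {
  stopifnot(m >= 2)
  enc <- encode_analysis_matrix(data)
  X <- enc$X
  miss <- is.na(X)
  bad <- grepl("_fu$", colnames(X))
  if (any(miss[, !bad, drop = FALSE])) {
    stop("missingness must be confined to follow-up (*_fu) fields",
         call. = FALSE)
  }
  miss_map <- which(miss, arr.ind = TRUE)
  miss_tbl <- tibble::tibble(row = unname(miss_map[, 1]),
                             column = colnames(X)[miss_map[, 2]])

  if (!any(miss)) {
    return(structure(
      list(datasets = replicate(m, data, simplify = FALSE), m = m,
           seed = as.integer(seed), missing_map = miss_tbl,
           em_iterations = integer(0)),
      class = "imputation_set"
    ))
  }

  # model only variables with variance; constants are restored untouched
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sds) & sds > 0
  if (any(miss[, !keep, drop = FALSE])) {
    # a constant, partially missing column: impute with the constant
    for (j in which(!keep)) {
      X[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
    }
    miss <- is.na(X)
  }
  Z <- scale(X[, keep, drop = FALSE])
  ctr <- attr(Z, "scaled:center"); scl <- attr(Z, "scaled:scale")
  mz <- is.na(Z)

  set.seed(as.integer(seed))
  stream_seeds <- sample.int(.Machine$integer.max, m)
  datasets <- vector("list", m)
  iterations <- integer(m)
  n <- nrow(Z)

  for (k in seq_len(m)) {
    set.seed(stream_seeds[k])
    boot <- Z[sample.int(n, n, replace = TRUE), , drop = FALSE]
    fit <- em_mvnorm(boot, tol = tol, maxit = maxit, ridge = ridge)
    iterations[k] <- fit$iterations
    Zk <- Z
    pat_key <- apply(mz, 1L, function(r) paste(as.integer(r), collapse = ""))
    for (key in unique(pat_key[rowSums(mz) > 0])) {
      rows <- which(pat_key == key & rowSums(mz) > 0)
      mm <- mz[rows[1L], ]
      o <- !mm
      So <- fit$sigma[o, o, drop = FALSE]
      cho <- chol(So)
      B <- fit$sigma[mm, o, drop = FALSE] %*% chol2inv(cho)
      C <- fit$sigma[mm, mm, drop = FALSE] -
        B %*% fit$sigma[o, mm, drop = FALSE]
      C <- (C + t(C)) / 2
      dev <- sweep(Z[rows, o, drop = FALSE], 2L, fit$mu[o])
      cm <- matrix(fit$mu[mm], length(rows), sum(mm), byrow = TRUE) +
        dev %*% t(B)
      draws <- cm + mvtnorm::rmvnorm(length(rows), sigma = C)
      Zk[rows, mm] <- draws
    }
    Xk <- X
    Xk[, keep] <- sweep(sweep(Zk, 2L, scl, `*`), 2L, ctr, `+`)
    Xk[!is.na(X)] <- X[!is.na(X)]  # observed cells are never altered
    datasets[[k]] <- decode_analysis_matrix(Xk, enc, data)
  }

  structure(
    list(datasets = datasets, m = m, seed = as.integer(seed),
         missing_map = miss_tbl, em_iterations = iterations),
    class = "imputation_set"
  )
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", x$m, "| seed =", x$seed, "|",
      nrow(x$missing_map), "imputed cells over",
      nrow(x$datasets[[1]]), "participants\n")
  invisible(x)
}

# encode an analysis tibble as a numeric matrix (binaries as 0/1)
encode_analysis_matrix <- function(data) {
  binary <- list()
  cols <- setdiff(names(data), "id")
  mats <- lapply(cols, function(nm) {
    v <- data[[nm]]
    if (is.numeric(v)) return(as.numeric(v))
    if (is.logical(v)) { binary[[nm]] <<- "logical"; return(as.numeric(v)) }
    if (nm == "arm") { binary[[nm]] <<- "arm"; return(as.numeric(v == "IT")) }
    if (nm == "sex") { binary[[nm]] <<- "sex"; return(as.numeric(v == "F")) }
    NULL
  })
  keep <- !vapply(mats, is.null, logical(1))
  X <- do.call(cbind, mats[keep])
  colnames(X) <- cols[keep]
  list(X = X, binary = binary, dropped = cols[!keep])
}

decode_analysis_matrix <- function(X, enc, template) {
  out <- template
  bounds <- analysis_bounds()
  for (nm in colnames(X)) {
    v <- X[, nm]
    if (nm %in% names(enc$binary)) {
      b <- as.numeric(v >= 0.5)
      v <- switch(enc$binary[[nm]],
                  logical = as.logical(b),
                  arm = ifelse(b == 1, "IT", "IS"),
                  sex = ifelse(b == 1, "F", "M"))
    } else if (nm %in% names(bounds)) {
      v <- pmin(pmax(v, bounds[[nm]][1]), bounds[[nm]][2])
    }
    out[[nm]] <- v
  }
  out
}

#' Pool means across imputations by Rubin's rules
#'
#' The pooled estimate is the arithmetic mean of the per-imputation
#' estimates; total variance is the within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance.
#'
#' @param estimates Per-imputation point estimates (length m >= 2).
#' @param variances Their squared standard errors (same length).
#' @return A one-row tibble: `estimate`, `within_var`, `between_var`,
#'   `total_var`, `se`, `m`.
#' @export
#' @examples
#' pool_means(c(1, 2, 3), c(1, 1, 1)) # estimate 2, total_var 2.333
pool_means <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length", call. = FALSE)
  }
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs m >= 2 imputations", call. = FALSE)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  tibble::tibble(
    estimate = mean(estimates),
    within_var = within,
    between_var = between,
    total_var = total,
    se = sqrt(total),
    m = m
  )
}

#' Pool by appending imputation-specific draws
#'
#' Medians, percentile intervals and acceptability curves are computed on the
#' concatenation of the per-imputation draw collections (e.g. 5 x 1000
#' bootstrap draws give one 5000-draw distribution), with imputation
#' provenance retained.
#'
#' @param per_imputation_draws Non-empty list of data frames (or atomic
#'   vectors) of draws, one element per imputation.
#' @return A tibble with an `imputation` label column; rows are the
#'   concatenated draws.
#' @export
pool_by_appending <- function(per_imputation_draws) {
  if (length(per_imputation_draws) == 0) {
    stop("no imputation draws to append", call. = FALSE)
  }
  labels <- names(per_imputation_draws) %||% seq_along(per_imputation_draws)
  pieces <- purrr::map2(per_imputation_draws, labels, function(d, lab) {
    if (is.atomic(d) && is.null(dim(d))) d <- tibble::tibble(value = d)
    if (nrow(d) == 0) stop("empty draw collection", call. = FALSE)
    dplyr::mutate(tibble::as_tibble(d), imputation = lab, .before = 1)
  })
  dplyr::bind_rows(pieces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an imputation set as a directory of CSV files
#'
#' Writes `imputation_1.csv` ... `imputation_m.csv`, `missing_map.csv` and a
#' `manifest.json` recording seed, m and EM iteration counts.
#'
#' @param set An [impute_trial()] result.
#' @param dir Output directory (created if needed).
#' @export
write_imputation_set <- function(set, dir) {
  stopifnot(inherits(set, "imputation_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(set$m)) {
    readr::write_csv(set$datasets[[k]],
                     file.path(dir, sprintf("imputation_%d.csv", k)), na = "")
  }
  readr::write_csv(set$missing_map, file.path(dir, "missing_map.csv"))
  jsonlite::write_json(
    list(m = set$m, seed = set$seed, em_iterations = set$em_iterations),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_imputation_set
#' @export
read_imputation_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  datasets <- lapply(seq_len(manifest$m), function(k) {
    readr::read_csv(file.path(dir, sprintf("imputation_%d.csv", k)),
                    show_col_types = FALSE, na = c("", "NA"))
  })
  structure(
    list(datasets = datasets, m = manifest$m, seed = manifest$seed,
         missing_map = readr::read_csv(file.path(dir, "missing_map.csv"),
                                       show_col_types = FALSE),
         em_iterations = manifest$em_iterations),
    class = "imputation_set"
  )
}
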