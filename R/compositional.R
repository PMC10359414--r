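#' Isometric log-ratio (pivot-coordinate) transform
#'
#' Maps a D-part composition to D-1 unconstrained coordinates using the
#' pivot (sequential binary partition) basis in the given part order:
#' \deqn{z_i = \sqrt{\tfrac{D-i}{D-i+1}}\,
#'   \ln\!\frac{x_i}{g(x_{i+1},\dots,x_D)}}
#' with \eqn{g} the geometric mean. Zeros are handled by multiplicative
#' replacement first: parts below `eps` are set to `eps` and the remaining
#' parts rescaled so the vector stays on the simplex. The transform is a
#' bijection of the open simplex onto \eqn{R^{D-1}}; [ilr_inverse()] inverts
#' it exactly.
#'
#' @param x A composition (non-negative vector summing to 1) or a matrix /
#'   data frame with one composition per row.
#' @param eps Multiplicative zero-replacement floor (default 1e-3); must be
#'   positive.
#' @return A numeric vector of length D-1, or a matrix with D-1 columns.
#' @examples
#' ilr_transform(rep(1 / 7, 7)) # all zeros
#' @export
ilr_transform <- function(x, eps = 1e-3) {
  if (eps <= 0) stop_paircn("eps must be > 0", "paircn_config_error")
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, ilr_transform, eps = eps))
    colnames(out) <- paste0("z", seq_len(ncol(out)))
    return(out)
  }
  check_simplex(x, what = "composition")
  x <- multiplicative_replace(x, eps)
  V <- ilr_basis(length(x))
  drop(crossprod(V, log(x)))
}

#' @rdname ilr_transform
#' @param z A coordinate vector of length D-1 (or matrix with one vector per
#'   row).
#' @export
ilr_inverse <- function(z) {
  if (is.matrix(z)) {
    return(t(apply(z, 1, ilr_inverse)))
  }
  V <- ilr_basis(length(z) + 1)
  y <- drop(V %*% z)
  e <- exp(y - max(y))
  e / sum(e)
}

# Orthonormal pivot-coordinate basis: D x (D-1), column i contrasts part i
# against the geometric mean of parts i+1..D.
ilr_basis <- function(D) {
  V <- matrix(0, D, D - 1)
  for (i in seq_len(D - 1)) {
    r <- D - i
    V[i, i] <- sqrt(r / (r + 1))
    V[(i + 1):D, i] <- -sqrt(r / (r + 1)) / r
  }
  V
}

multiplicative_replace <- function(x, eps) {
  low <- x < eps
  if (!any(low)) return(x)
  if (all(low)) return(rep(1 / length(x), length(x)))
  x[low] <- eps
  x[!low] <- x[!low] * (1 - sum(low) * eps) / sum(x[!low])
  x / sum(x)
}

#' Global differential abundance of signature exposures
#'
#' Tests whether the signature-exposure composition differs between two
#' groups, respecting both the compositional constraint (exposures sum to 1)
#' and the repeated-measures structure (multiple samples per patient).
#' Exposures are mapped to isometric log-ratio coordinates
#' ([ilr_transform()]); per coordinate, a linear model with a fixed group
#' effect and a random patient intercept is fitted; the global Wald test asks
#' whether all group slopes are jointly zero.
#'
#' The joint covariance of the slope estimates and the reference distribution
#' depend on the design, detected automatically:
#' \itemize{
#' \item paired (every patient has exactly one sample per group): the
#'   mixed-model slope estimate equals the mean within-patient coordinate
#'   difference, whose joint covariance is estimated from the per-patient
#'   difference vectors; the Wald statistic is referred to its exact
#'   small-sample F distribution (Hotelling form).
#' \item one sample per patient: fixed-effects (two-sample) form with pooled
#'   covariance and the corresponding F reference; a note records that the
#'   random intercept is not identifiable.
#' \item otherwise: per-coordinate `lme4` fits; the slope covariance couples
#'   the model-based standard errors with the residual correlation across
#'   coordinates, and the Wald statistic is referred to chi-square. Singular
#'   random-effect fits fall back to fixed effects with a recorded warning.
#' }
#'
#' Excluding a signature (e.g. one suspected of tracking a fixation
#' artefact) renormalises the remaining subcomposition before the transform.
#'
#' @param exposures Tibble with patient and group columns plus one column per
#'   signature (`s1`..`s7` by default).
#' @param group_col,patient_col Column names (defaults `"role"`,
#'   `"patient_id"`).
#' @param sig_cols Signature columns (default: all columns matching
#'   `^s[0-9]+$`).
#' @param exclude Signatures to drop before the transform (names or indices),
#'   or `NULL`.
#' @param eps Zero-replacement floor passed to [ilr_transform()].
#' @param engine `"auto"` (default; closed form for paired/two-sample
#'   designs), `"lmm"` (force per-coordinate `lme4` fits), or `"closed"`.
#' @return An `ilr_fit` object; see [tidy()], [glance()],
#'   [inverse_ilr_group_means()].
#' @export
fit_global_abundance_model <- function(exposures, group_col = "role",
                                       patient_col = "patient_id",
                                       sig_cols = NULL, exclude = NULL,
                                       eps = 1e-3,
                                       engine = c("auto", "lmm", "closed")) {
  engine <- match.arg(engine)
  if (is.null(sig_cols)) {
    sig_cols <- grep("^s[0-9]+$", names(exposures), value = TRUE)
  }
  if (!is.null(exclude)) {
    if (is.numeric(exclude)) exclude <- sig_cols[exclude]
    sig_cols <- setdiff(sig_cols, exclude)
  }
  if (length(sig_cols) < 3) {
    stop_paircn("need at least 3 signatures (2 coordinates) after exclusion",
                "paircn_config_error")
  }
  stopifnot(group_col %in% names(exposures), patient_col %in% names(exposures))
  E <- as.matrix(exposures[, sig_cols])
  E <- E / rowSums(E) # renormalise the (sub)composition
  Z <- ilr_transform(E, eps = eps)
  p <- ncol(Z)
  grp <- factor(exposures[[group_col]])
  if (nlevels(grp) != 2) {
    stop_paircn("grouping must have exactly 2 levels", "paircn_config_error")
  }
  pat <- as.character(exposures[[patient_col]])
  tab <- table(pat, grp)
  paired <- all(tab == 1)
  single <- all(rowSums(tab) == 1)
  notes <- character(0)

  if (engine == "closed" && !(paired || single)) {
    stop_paircn("closed-form engine requires a paired or one-sample-per-patient design",
                "paircn_config_error")
  }
  use_closed <- engine %in% c("auto", "closed") && (paired || single)

  if (use_closed && paired) {
    pats <- rownames(tab)
    z1 <- Z[match(paste0(pats, levels(grp)[1]), paste0(pat, grp)), , drop = FALSE]
    z2 <- Z[match(paste0(pats, levels(grp)[2]), paste0(pat, grp)), , drop = FALSE]
    d <- z2 - z1
    n <- nrow(d)
    beta1 <- colMeans(d)
    beta0 <- colMeans(z1)
    vd <- apply(d, 2, var)
    vm <- apply((z1 + z2) / 2, 2, var)
    var_resid <- vd / 2
    var_patient <- pmax(vm - vd / 4, 0)
    if (all(abs(d) < 1e-12)) {
      W <- 0
      pval <- 1
      df2 <- n - p
    } else {
      S <- cov(d)
      Sinv <- tryCatch(solve(S), error = function(e) {
        notes <<- c(notes, "singular difference covariance; pseudo-inverse used")
        MASS::ginv(S)
      })
      W <- n * drop(t(beta1) %*% Sinv %*% beta1)
      df2 <- n - p
      if (df2 < 1) {
        stop_paircn("too few patients for the joint Wald test", "paircn_fit_error")
      }
      Fstat <- (n - p) / (p * (n - 1)) * W
      pval <- pf(Fstat, p, df2, lower.tail = FALSE)
    }
    fit_engine <- "closed-paired"
    nobs <- c(n, n)
  } else if (use_closed && single) {
    notes <- c(notes,
               "one sample per patient: random intercept not identifiable; fixed-effects form used")
    g1 <- Z[grp == levels(grp)[1], , drop = FALSE]
    g2 <- Z[grp == levels(grp)[2], , drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    if (min(n1, n2) < 2) {
      stop_paircn("each group needs at least 2 samples", "paircn_fit_error")
    }
    beta0 <- colMeans(g1)
    beta1 <- colMeans(g2) - beta0
    Sp <- ((n1 - 1) * cov(g1) + (n2 - 1) * cov(g2)) / (n1 + n2 - 2)
    var_resid <- diag(Sp)
    var_patient <- rep(NA_real_, p)
    if (all(abs(beta1) < 1e-12)) {
      W <- 0; pval <- 1; df2 <- n1 + n2 - p - 1
    } else {
      V <- Sp * (1 / n1 + 1 / n2)
      Vinv <- tryCatch(solve(V), error = function(e) {
        notes <<- c(notes, "singular pooled covariance; pseudo-inverse used")
        MASS::ginv(V)
      })
      W <- drop(t(beta1) %*% Vinv %*% beta1)
      df2 <- n1 + n2 - p - 1
      if (df2 < 1) {
        stop_paircn("too few samples for the joint Wald test", "paircn_fit_error")
      }
      Fstat <- df2 / (p * (n1 + n2 - 2)) * W
      pval <- pf(Fstat, p, df2, lower.tail = FALSE)
    }
    fit_engine <- "closed-two-sample"
    nobs <- c(n1, n2)
  } else {
    # general case: per-coordinate linear mixed models
    beta0 <- beta1 <- se1 <- var_patient <- var_resid <- numeric(p)
    resid_mat <- matrix(NA_real_, nrow(Z), p)
    fell_back <- FALSE
    for (cc in seq_len(p)) {
      dat <- data.frame(z = Z[, cc], group = grp, patient = pat)
      fit <- tryCatch(
        lme4::lmer(z ~ group + (1 | patient), data = dat, REML = TRUE),
        error = function(e) NULL, warning = function(w) NULL
      )
      singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
      if (singular) {
        fell_back <- TRUE
        lfit <- stats::lm(z ~ group, data = dat)
        beta0[cc] <- coef(lfit)[1]
        beta1[cc] <- coef(lfit)[2]
        se1[cc] <- sqrt(vcov(lfit)[2, 2])
        var_patient[cc] <- 0
        var_resid[cc] <- summary(lfit)$sigma^2
        resid_mat[, cc] <- residuals(lfit)
      } else {
        fe <- lme4::fixef(fit)
        beta0[cc] <- fe[1]
        beta1[cc] <- fe[2]
        se1[cc] <- sqrt(as.matrix(vcov(fit))[2, 2])
        vc <- as.data.frame(lme4::VarCorr(fit))
        var_patient[cc] <- vc$vcov[vc$grp == "patient"]
        var_resid[cc] <- vc$vcov[vc$grp == "Residual"]
        resid_mat[, cc] <- residuals(fit)
      }
    }
    if (fell_back) {
      notes <- c(notes, "singular random-effect fit; fixed-effects fallback for some coordinates")
    }
    R <- suppressWarnings(stats::cor(resid_mat))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    V <- diag(se1, p) %*% R %*% diag(se1, p)
    Vinv <- tryCatch(solve(V), error = function(e) MASS::ginv(V))
    W <- drop(t(beta1) %*% Vinv %*% beta1)
    pval <- pchisq(W, df = p, lower.tail = FALSE)
    df2 <- Inf
    fit_engine <- "lmm"
    nobs <- as.integer(table(grp))
  }

  structure(
    list(
      coefficients = tibble(coordinate = paste0("z", seq_len(p)),
                            beta0 = unname(beta0), beta1 = unname(beta1),
                            var_patient = unname(var_patient),
                            var_resid = unname(var_resid)),
      wald = list(statistic = W, df1 = p, df2 = df2, p.value = pval),
      signatures = sig_cols, excluded = exclude, eps = eps,
      groups = levels(grp), n = nobs, engine = fit_engine, notes = notes
    ),
    class = "ilr_fit"
  )
}

#' @export
#' @method print ilr_fit
print.ilr_fit <- function(x, ...) {
  cat(sprintf(
    "<ilr_fit> %s vs %s on %d coordinates (%s)\n  Wald W = %.3f, p = %.4g\n",
    x$groups[1], x$groups[2], x$wald$df1, x$engine,
    x$wald$statistic, x$wald$p.value))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Group-mean compositions from a fitted abundance model
#'
#' Back-transforms the fitted per-coordinate intercepts (reference group) and
#' intercept-plus-slope (comparison group) through the inverse isometric
#' log-ratio transform, giving one composition per group on the signatures
#' the model was fitted on.
#'
#' @param fit An `ilr_fit` from [fit_global_abundance_model()].
#' @return Tibble `group`, one column per signature.
#' @export
inverse_ilr_group_means <- function(fit) {
  stopifnot(inherits(fit, "ilr_fit"))
  m1 <- ilr_inverse(fit$coefficients$beta0)
  m2 <- ilr_inverse(fit$coefficients$beta0 + fit$coefficients$beta1)
  out <- as_tibble(rbind(m1, m2), .name_repair = ~ fit$signatures)
  mutate(out, group = fit$groups, .before = 1)
}
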