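# Bayes-factor machinery: JZS t-tests by adaptive quadrature and default
# g-prior Bayes factors for factorial linear models with participants as a
# random nuisance factor, estimated by Monte-Carlo integration over the
# per-batch g parameters with a closed-form conditional marginal likelihood.
# All Bayes factors are stored and reported on the natural-log scale.

#' JZS Bayesian t-test (log Bayes factor)
#'
#' Computes the natural-log Bayes factor BF10 for a one-sample (or paired)
#' t-test comparing H1: delta ~ Cauchy(0, r) against the point null
#' H0: delta = 0, by numerical integration of the marginal likelihood over
#' g ~ InverseGamma(1/2, r^2/2).
#'
#' @param differences Numeric vector of (paired) differences.  Alternatively
#'   pass `t` and `n` directly and leave `differences` as `NULL`.
#' @param r Cauchy prior scale on the standardized effect size
#'   (default 0.707).
#' @param t,n t statistic and sample size, used when `differences` is `NULL`.
#' @return Natural-log BF10 (scalar).
#' @export
#' @examples
#' jzs_ttest_logbf(t = 3, n = 40)
jzs_ttest_logbf <- function(differences = NULL, r = 0.707, t = NULL, n = NULL) {
  stopifnot(r > 0)
  if (!is.null(differences)) {
    n <- length(differences)
    if (n < 2) abort("need at least 2 observations")
    s <- sd(differences)
    if (s == 0) abort("zero-variance input: the t statistic is undefined")
    t <- mean(differences) / (s / sqrt(n))
  }
  stopifnot(!is.null(t), !is.null(n), n >= 2)
  nu <- n - 1
  # log integrand on log(g) scale (change of variables stabilizes the tails)
  log_joint <- function(logg) {
    g <- exp(logg)
    dens <- 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * logg - r^2 / (2 * g)
    lik <- -0.5 * log1p(n * g) -
      ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu))
    dens + lik + logg                      # + logg: Jacobian of g = exp(logg)
  }
  # normalize by the integrand's maximum for a well-scaled quadrature
  opt <- stats::optimize(function(lg) -log_joint(lg), c(-25, 25))
  m <- -opt$objective
  f <- function(lg) exp(log_joint(lg) - m)
  int <- integrate(f, -40, 40, rel.tol = 1e-10, abs.tol = 0)
  log_m1 <- m + log(int$value)
  log_m0 <- -((nu + 1) / 2) * log1p(t^2 / nu)
  log_m1 - log_m0
}

#' Prior specification for Bayes-factor linear models
#'
#' @param r_fixed Cauchy scale for the effects of interest (design terms);
#'   one of the conventional values 0.5, 0.707, 1, or any positive number.
#' @param r_random Scale for the participant nuisance batch (default 1,
#'   not varied with `r_fixed`).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(r_fixed = 0.707, r_random = 1) {
  stopifnot(r_fixed > 0, r_random > 0)
  structure(list(location_delta = 0, r_fixed = r_fixed, r_random = r_random),
            class = "prior_spec")
}

# closed set of admissible design terms (order fixed for reporting)
DESIGN_TERMS <- c("size", "contrast", "emotion",
                  "size:contrast", "size:emotion", "contrast:emotion",
                  "size:contrast:emotion")

#' Model specification over the factorial design terms
#'
#' @param terms Character subset of the closed term set `size`, `contrast`,
#'   `emotion`, `size:contrast`, `size:emotion`, `contrast:emotion`,
#'   `size:contrast:emotion`.  Arbitrary (non-marginal) subsets are allowed
#'   to support top-down omission.  The empty set is the null model; every
#'   model keeps the participant random factor.
#' @param label Optional display label.
#' @return A `model_spec` object.
#' @export
model_spec <- function(terms, label = NULL) {
  terms <- as.character(terms)
  bad <- setdiff(terms, DESIGN_TERMS)
  if (length(bad) > 0) {
    abort(paste0("unknown design term(s): ", paste(bad, collapse = ", ")))
  }
  terms <- DESIGN_TERMS[DESIGN_TERMS %in% terms]
  structure(
    list(terms = terms, includes_participant_random = TRUE,
         label = label %||% if (length(terms) == 0) "null" else
           paste(terms, collapse = " + ")),
    class = "model_spec"
  )
}

# interaction notation "A x B" expands to mains + lower-order interactions
expand_interactive <- function(factors) {
  k <- length(factors)
  terms <- character(0)
  for (ord in seq_len(k)) {
    combs <- utils::combn(factors, ord, simplify = FALSE)
    terms <- c(terms, vapply(combs, paste, "", collapse = ":"))
  }
  terms
}

#' The six candidate theory models
#'
#' Three additive models (`size + emotion`, `contrast + emotion`,
#' `size + contrast + emotion`) and three interactive models
#' (`size x emotion`, `contrast x emotion`, `size x contrast x emotion`),
#' where an interactive model contains its constituent main effects and all
#' lower-order interactions.
#'
#' @return Named list of [model_spec()] objects.
#' @export
candidate_models <- function() {
  list(
    "size + emotion" = model_spec(c("size", "emotion"), "size + emotion"),
    "contrast + emotion" = model_spec(c("contrast", "emotion"),
                                      "contrast + emotion"),
    "size + contrast + emotion" = model_spec(c("size", "contrast", "emotion"),
                                             "size + contrast + emotion"),
    "size x emotion" = model_spec(expand_interactive(c("size", "emotion")),
                                  "size x emotion"),
    "contrast x emotion" = model_spec(expand_interactive(c("contrast", "emotion")),
                                      "contrast x emotion"),
    "size x contrast x emotion" = model_spec(
      expand_interactive(c("size", "contrast", "emotion")),
      "size x contrast x emotion")
  )
}

# orthonormal sum-to-zero codes for a 2-level factor: +1/sqrt(2), -1/sqrt(2)
two_level_code <- function(values, levels) {
  ifelse(values == levels[1], 1, -1) / sqrt(2)
}

# build the centred design pieces for one amplitude table:
# y, per-term columns, participant columns, batch bookkeeping
build_design <- function(table, require_full = TRUE) {
  need <- c("subject_id", "emotion", "size", "contrast", "amplitude_uV")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    abort(paste0("amplitude table misses column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if ("component" %in% names(table) &&
      length(unique(table$component)) > 1) {
    abort("amplitude table contains multiple components; fit one at a time")
  }
  cells <- cell_index(table$emotion, table$size, table$contrast)
  if (require_full && length(unique(cells)) < 8) {
    abort("all eight design cells must be present")
  }
  subj <- factor(table$subject_id)
  if (nlevels(subj) < 2) abort("need at least 2 participants")

  main <- list(
    size = two_level_code(table$size, SIZE_LEVELS),
    contrast = two_level_code(table$contrast, CONTRAST_LEVELS),
    emotion = two_level_code(table$emotion, EMOTION_LEVELS)
  )
  cols <- list()
  for (term in DESIGN_TERMS) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    # Kronecker product of the per-factor orthonormal codes
    cols[[term]] <- matrix(Reduce(`*`, main[parts]), ncol = 1)
  }
  # orthonormal subject codes: basis of the sum-to-zero subspace
  ns <- nlevels(subj)
  H <- cbind(rep(1, ns) / sqrt(ns), stats::contr.helmert(ns))
  H[, -1] <- sweep(H[, -1, drop = FALSE], 2,
                   sqrt(colSums(H[, -1, drop = FALSE]^2)), "/")
  subj_cols <- H[as.integer(subj), -1, drop = FALSE]

  y <- table$amplitude_uV
  list(y = y - mean(y), cols = cols, subj_cols = subj_cols, n = length(y))
}

# log marginal likelihood (relative to the intercept-only model) of one
# g-prior model, by Monte-Carlo over per-batch g draws.
# batches: list of (cols matrix, r scale); returns log-mean and batch SE.
g_prior_log_marginal <- function(y, batch_cols, batch_r, n_iterations, seed,
                                 n_batches = 100) {
  n <- length(y)
  X <- do.call(cbind, batch_cols)
  p <- ncol(X)
  X <- sweep(X, 2, colMeans(X))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  if (yty == 0) abort("response has zero variance")
  batch_of <- rep(seq_along(batch_cols),
                  vapply(batch_cols, ncol, integer(1)))
  nb <- length(batch_cols)
  set.seed(seed)
  g_draws <- matrix(1 / rgamma(n_iterations * nb, shape = 0.5,
                               rate = rep(batch_r^2 / 2, each = n_iterations)),
                    nrow = n_iterations)
  logm <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    gcol <- g_draws[i, batch_of]
    W <- XtX + diag(1 / gcol, p)
    R <- chol(W)
    logdet <- sum(log(gcol)) + 2 * sum(log(diag(R)))
    q <- backsolve(R, forwardsolve(t(R), Xty))
    rss_ratio <- (yty - sum(Xty * q)) / yty
    logm[i] <- -0.5 * logdet - ((n - 1) / 2) * log(rss_ratio)
  }
  log_mean <- logsumexp(logm) - log(n_iterations)
  # relative Monte-Carlo SE from batch means
  k <- max(2L, min(n_batches, n_iterations))
  grp <- rep(seq_len(k), length.out = n_iterations)
  bmeans <- vapply(seq_len(k), function(j) {
    logsumexp(logm[grp == j]) - log(sum(grp == j))
  }, numeric(1))
  ratios <- exp(bmeans - log_mean)
  rel_se <- sd(ratios) / sqrt(k)
  list(log_marginal = log_mean, rel_se = rel_se)
}

#' Default g-prior Bayes factor of a factorial model versus the null
#'
#' Computes the natural-log Bayes factor of `model` against the null model
#' (grand mean + participant random factor) for single-trial amplitudes of
#' one component.  Every design term forms its own effect batch with
#' orthonormal sum-to-zero contrast codes and prior
#' `theta_b ~ N(0, g_b sigma^2)`, `g_b ~ InverseGamma(1/2, r^2/2)` with
#' `r = r_fixed`; the participant batch uses `r_random`.  The grand mean and
#' `sigma^2` receive the noninformative prior; conditional on the `g`s the
#' marginal likelihood is closed-form and the `g` integral is estimated by
#' Monte-Carlo sampling from the priors.  The proportional error is the
#' batch-means relative standard error of the BF estimate, in percent.
#'
#' @param table Amplitude tibble (one component): columns `subject_id`,
#'   `emotion`, `size`, `contrast`, `amplitude_uV`.
#' @param model A [model_spec()].
#' @param prior A [prior_spec()].
#' @param n_iterations Monte-Carlo draws from the g priors (default 100000).
#' @param seed Integer seed; results are deterministic given it.
#' @return A one-row tibble: `model`, `r`, `log_bf10`, `pe_pct`,
#'   `n_iterations`, `seed`.
#' @export
linear_model_logbf <- function(table, model, prior = prior_spec(),
                               n_iterations = 100000, seed = 1) {
  stopifnot(inherits(model, "model_spec"), inherits(prior, "prior_spec"))
  if (length(model$terms) == 0) {
    return(tibble(model = model$label, r = prior$r_fixed, log_bf10 = 0,
                  pe_pct = 0, n_iterations = as.integer(n_iterations),
                  seed = as.integer(seed)))
  }
  des <- build_design(table, require_full = FALSE)
  for (f in unique(unlist(strsplit(model$terms, ":", fixed = TRUE)))) {
    if (length(unique(table[[f]])) < 2) {
      abort(sprintf("factor %s has fewer than 2 levels in the table", f))
    }
  }
  num <- model_log_marginal(des, model$terms, prior, n_iterations, seed)
  den <- null_log_marginal(des, prior, n_iterations, seed)
  tibble(
    model = model$label, r = prior$r_fixed,
    log_bf10 = num$log_marginal - den$log_marginal,
    pe_pct = 100 * sqrt(num$rel_se^2 + den$rel_se^2),
    n_iterations = as.integer(n_iterations), seed = as.integer(seed)
  )
}

model_log_marginal <- function(des, terms, prior, n_iterations, seed) {
  batch_cols <- c(des$cols[terms], list(participant = des$subj_cols))
  batch_r <- c(rep(prior$r_fixed, length(terms)), prior$r_random)
  g_prior_log_marginal(des$y, batch_cols, batch_r, n_iterations, seed)
}

null_log_marginal <- function(des, prior, n_iterations, seed) {
  g_prior_log_marginal(des$y, list(participant = des$subj_cols),
                       prior$r_random, n_iterations, seed + 1L)
}

#' Compare the six candidate models against the null
#'
#' Evaluates each theory model of [candidate_models()] against the
#' participant-only null at each requested prior scale, sharing one estimate
#' of the null marginal per scale.  Rows are sorted by decreasing log BF
#' within each component and scale.
#'
#' @param table Amplitude tibble; may contain several components.
#' @param r_fixed Numeric vector of prior scales (default `c(0.5, 0.707, 1)`).
#' @param r_random Participant-batch scale (default 1).
#' @param n_iterations,seed Monte-Carlo settings.
#' @param models Optional named list of [model_spec()]s overriding the
#'   default six.
#' @return A `bf_comparison` tibble: `component`, `model`, `r`, `log_bf10`,
#'   `pe_pct`, `n_iterations`, `seed`, `rank`, `log_bf_best_vs_second`
#'   (repeated within each component x r group).
#' @export
compare_candidate_models <- function(table, r_fixed = c(0.5, 0.707, 1),
                                     r_random = 1, n_iterations = 100000,
                                     seed = 1, models = candidate_models()) {
  comps <- if ("component" %in% names(table))
    unique(table$component) else "amplitude"
  out <- list()
  for (comp in comps) {
    sub <- if ("component" %in% names(table)) {
      table[table$component == comp, ]
    } else table
    des <- build_design(sub)
    den <- null_log_marginal(des, prior_spec(r_random = r_random),
                             n_iterations, seed)
    for (r in r_fixed) {
      pr <- prior_spec(r_fixed = r, r_random = r_random)
      rows <- purrr::imap(models, function(mod, nm) {
        num <- model_log_marginal(des, mod$terms, pr, n_iterations, seed)
        tibble(
          component = comp, model = mod$label, r = r,
          log_bf10 = num$log_marginal - den$log_marginal,
          pe_pct = 100 * sqrt(num$rel_se^2 + den$rel_se^2),
          n_iterations = as.integer(n_iterations), seed = as.integer(seed)
        )
      })
      block <- bind_rows(rows) |> arrange(desc(.data$log_bf10))
      block$rank <- seq_len(nrow(block))
      block$log_bf_best_vs_second <- block$log_bf10[1] - block$log_bf10[2]
      out[[length(out) + 1]] <- block
    }
  }
  res <- bind_rows(out)
  class(res) <- c("bf_comparison", class(res))
  res
}

#' Top-down term omission from the full model
#'
#' Starting from the full factorial model (all three mains, three two-way
#' and the three-way interaction), removes one term at a time while
#' retaining all others, and reports the log Bayes factor of the reduced
#' model against the full model (positive values mean the omission improves
#' the fit).  The participant-only null cancels in this ratio.
#'
#' @inheritParams compare_candidate_models
#' @return An `bf_omission` tibble: `component`, `omitted_term`, `r`,
#'   `log_bf_omission`, `pe_pct`, `n_iterations`, `seed`.
#' @export
topdown_term_omission <- function(table, r_fixed = c(0.5, 0.707, 1),
                                  r_random = 1, n_iterations = 100000,
                                  seed = 1) {
  comps <- if ("component" %in% names(table))
    unique(table$component) else "amplitude"
  out <- list()
  for (comp in comps) {
    sub <- if ("component" %in% names(table)) {
      table[table$component == comp, ]
    } else table
    des <- build_design(sub)
    for (r in r_fixed) {
      pr <- prior_spec(r_fixed = r, r_random = r_random)
      full <- model_log_marginal(des, DESIGN_TERMS, pr, n_iterations, seed)
      rows <- lapply(DESIGN_TERMS, function(term) {
        red <- model_log_marginal(des, setdiff(DESIGN_TERMS, term), pr,
                                  n_iterations, seed)
        tibble(
          component = comp, omitted_term = term, r = r,
          log_bf_omission = red$log_marginal - full$log_marginal,
          pe_pct = 100 * sqrt(red$rel_se^2 + full$rel_se^2),
          n_iterations = as.integer(n_iterations), seed = as.integer(seed)
        )
      })
      out[[length(out) + 1]] <- bind_rows(rows)
    }
  }
  res <- bind_rows(out)
  class(res) <- c("bf_omission", class(res))
  res
}

#' Post-hoc Bayesian emotion contrasts per size x contrast cell
#'
#' For each size x contrast combination, aggregates single trials to one
#' mean per subject and emotion, forms the paired negative-minus-neutral
#' differences, and applies the JZS t-test at each prior scale.
#'
#' @param table Amplitude tibble; may contain several components.
#' @param r Numeric vector of Cauchy scales (default `c(0.5, 0.707, 1)`).
#' @return A `bf_posthoc` tibble: `component`, `size`, `contrast`, `cell`,
#'   `r`, `log_bf10`, `n_subjects`.
#' @export
posthoc_emotion_contrasts <- function(table, r = c(0.5, 0.707, 1)) {
  stopifnot(all(c("subject_id", "emotion", "size", "contrast",
                  "amplitude_uV") %in% names(table)))
  if (!"component" %in% names(table)) table$component <- "amplitude"
  means <- table |>
    filter(.data$emotion %in% EMOTION_LEVELS) |>
    group_by(.data$component, .data$size, .data$contrast,
             .data$subject_id, .data$emotion) |>
    summarise(m = mean(.data$amplitude_uV), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "emotion",
                             values_from = "m")
  if (!all(EMOTION_LEVELS %in% names(wide))) {
    abort("both emotion levels are required in every size x contrast cell")
  }
  groups <- wide |>
    group_by(.data$component, .data$size, .data$contrast) |>
    tidyr::nest(.key = "data") |>
    ungroup()
  rows <- purrr::pmap(groups, function(component, size, contrast, data) {
    d <- data$negative - data$neutral
    if (anyNA(d)) abort("a subject lacks one emotion level in a cell")
    purrr::map(r, function(ri) {
      tibble(
        component = component, size = size, contrast = contrast,
        cell = paste0(size, " size, ", contrast,
                      " contrast, negative vs. neutral"),
        r = ri,
        log_bf10 = jzs_ttest_logbf(d, r = ri),
        n_subjects = length(d)
      )
    }) |> bind_rows()
  })
  res <- bind_rows(rows) |>
    arrange(.data$component, .data$r)
  class(res) <- c("bf_posthoc", class(res))
  res
}

#' Convert between log and natural-scale Bayes factors
#'
#' @param log_bf Natural-log Bayes factor(s).
#' @return Numeric vector on the natural scale.
#' @export
#' @examples
#' bf_from_log(-1.72)   # 0.18
bf_from_log <- function(log_bf) exp(log_bf)

#' @rdname bf_from_log
#' @param bf Natural-scale Bayes factor(s).
#' @export
log_from_bf <- function(bf) log(bf)
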