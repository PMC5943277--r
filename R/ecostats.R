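# Ecological indices and the statistical battery: yield response,
# commonness (Levins niche breadth), robustness, Bray-Curtis,
# PERMANOVA, correlation, stepwise-AIC multiple regression, and
# binomial mixed-effects logistic regression.

#' Yield response of inoculated plots
#'
#' For every inoculated plot,
#' `(yield - mean yield of matched control plots) / mean control yield`,
#' where the control mean is taken over the same trial (and the same P
#' level when `match_p_level = TRUE`, the design's natural pairing).
#'
#' @param metadata data.frame with columns `sample_id`, `trial`,
#'   `p_level`, `inoculated` (logical), `yield`.
#' @param match_p_level match controls within trial x P level (default)
#'   or trial-wide.
#' @return data.frame: `sample_id`, `trial`, `p_level`, `yield`,
#'   `control_mean`, `response`.
#' @export
yield_response <- function(metadata, match_p_level = TRUE) {
  need <- c("sample_id", "trial", "p_level", "inoculated", "yield")
  stopifnot(all(need %in% names(metadata)))
  inoc <- metadata[metadata$inoculated, ]
  ctl <- metadata[!metadata$inoculated, ]
  if (!nrow(inoc)) stop("no inoculated plots", call. = FALSE)
  key <- function(d) if (match_p_level)
    paste(d$trial, d$p_level) else as.character(d$trial)
  ctl_mean <- tapply(ctl$yield, key(ctl), mean)
  km <- key(inoc)
  if (any(!km %in% names(ctl_mean)))
    stop("inoculated plot(s) without matching control plots: ",
         paste(inoc$sample_id[!km %in% names(ctl_mean)], collapse = ", "),
         call. = FALSE)
  cm <- as.numeric(ctl_mean[km])
  if (any(cm == 0))
    stop("control mean yield is zero for: ",
         paste(unique(km[cm == 0]), collapse = ", "), call. = FALSE)
  data.frame(sample_id = inoc$sample_id, trial = inoc$trial,
             p_level = inoc$p_level, yield = inoc$yield,
             control_mean = cm, response = (inoc$yield - cm) / cm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Commonness (niche breadth) from trial mean abundances
#'
#' The Levins niche-breadth statistic `1 / sum(P^2)` where `P` are the
#' habitat (trial) shares of one OTU's mean read numbers. Ranges from 1
#' (perfect specialist) to the number of trials (even generalist).
#'
#' @param trial_means non-negative mean read numbers, one per trial.
#' @return the commonness value.
#' @export
#' @examples
#' commonness_index(c(100, 100, 100))  # 3: even generalist
#' commonness_index(c(60, 30, 10))     # 1 / 0.46
commonness_index <- function(trial_means) {
  stopifnot(all(trial_means >= 0))
  s <- sum(trial_means)
  if (s == 0) return(NA_real_)
  1 / sum((trial_means / s)^2)
}

#' Per-OTU commonness from a control-only rarefied OTU table
#'
#' Computes, for every retained indigenous OTU, the trial-share matrix
#' `P[i, j]` (mean read number of OTU j in trial i over the sum of its
#' trial means) and the commonness `1 / sum_i P[i,j]^2`. Only
#' uninoculated control samples should be supplied. OTUs whose mean
#' relative abundance is below `rare_filter` (default 0.2% of total
#' reads), inoculum-set OTUs, and OTUs with zero reads in every trial
#' are excluded; exclusions are reported in the result.
#'
#' @param table an `amf_otu_table` (control samples only) or a
#'   samples x OTUs count matrix.
#' @param trials trial id per sample (recycled against table rows).
#' @param inoculum_set OTU ids (or `amf_inoculum_set`) to exclude.
#' @param rare_filter mean relative-abundance threshold.
#' @return list of class `amf_commonness`: `commonness` (named vector),
#'   `P` (trials x OTUs share matrix), `excluded` (data.frame of OTU,
#'   reason).
#' @export
commonness <- function(table, trials, inoculum_set = NULL,
                       rare_filter = 0.002) {
  counts <- if (inherits(table, "amf_otu_table")) table$counts else table
  stopifnot(is.matrix(counts))
  trials <- rep_len(as.character(trials), nrow(counts))
  if (length(unique(trials)) < 2L)
    stop("commonness needs >= 2 trials", call. = FALSE)
  excl <- data.frame(otu_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  ids <- if (inherits(inoculum_set, "amf_inoculum_set"))
    inoculum_set$otu_ids else inoculum_set
  if (length(ids)) {
    hit <- intersect(colnames(counts), ids)
    excl <- rbind(excl, data.frame(
      otu_id = hit, reason = rep("inoculum_set", length(hit))))
    counts <- counts[, setdiff(colnames(counts), ids), drop = FALSE]
  }
  rel <- sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  rare <- colMeans(rel) < rare_filter
  excl <- rbind(excl, data.frame(
    otu_id = colnames(counts)[rare],
    reason = rep("rare", sum(rare))))
  counts <- counts[, !rare, drop = FALSE]
  M <- apply(counts, 2, function(col) tapply(col, trials, mean))
  zero <- colSums(M) == 0
  if (any(zero)) {
    excl <- rbind(excl, data.frame(
      otu_id = colnames(M)[zero],
      reason = rep("all_zero", sum(zero))))
    M <- M[, !zero, drop = FALSE]
  }
  P <- sweep(M, 2, colSums(M), "/")
  cm <- apply(M, 2, commonness_index)
  structure(list(commonness = cm, P = P, excluded = excl),
            class = "amf_commonness")
}

#' Robustness of indigenous OTUs against inoculation
#'
#' Per (OTU, trial): the ratio of the OTU's mean read abundance in
#' inoculated plots to that in control plots. A zero control mean makes
#' the ratio undefined; such entries are flagged, never silently zeroed.
#'
#' @param table an `amf_otu_table` (field samples) or count matrix.
#' @param metadata data.frame aligned by `sample_id` with `trial` and
#'   logical `inoculated`.
#' @param inoculum_set OTU ids (or `amf_inoculum_set`) to exclude.
#' @param rare_filter mean relative-abundance threshold applied on
#'   control samples, for the same OTU universe as [commonness()];
#'   set to 0 to disable.
#' @return data.frame: `otu_id`, `trial`, `mean_inoculated`,
#'   `mean_control`, `robustness`, logical `undefined`.
#' @export
robustness <- function(table, metadata, inoculum_set = NULL,
                       rare_filter = 0.002) {
  counts <- if (inherits(table, "amf_otu_table")) table$counts else table
  idx <- match(rownames(counts), metadata$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  meta <- metadata[idx, ]
  ids <- if (inherits(inoculum_set, "amf_inoculum_set"))
    inoculum_set$otu_ids else inoculum_set
  if (length(ids))
    counts <- counts[, setdiff(colnames(counts), ids), drop = FALSE]
  if (rare_filter > 0) {
    ctl <- counts[!meta$inoculated, , drop = FALSE]
    rel <- sweep(ctl, 1, pmax(rowSums(ctl), 1), "/")
    counts <- counts[, colMeans(rel) >= rare_filter, drop = FALSE]
  }
  out <- list()
  for (tr in unique(meta$trial)) {
    sel <- meta$trial == tr
    if (!any(sel & meta$inoculated) || !any(sel & !meta$inoculated))
      stop("trial ", tr, " lacks one of the treatments", call. = FALSE)
    mi <- colMeans(counts[sel & meta$inoculated, , drop = FALSE])
    mc <- colMeans(counts[sel & !meta$inoculated, , drop = FALSE])
    out[[tr]] <- data.frame(
      otu_id = colnames(counts), trial = tr,
      mean_inoculated = as.numeric(mi), mean_control = as.numeric(mc),
      robustness = ifelse(mc > 0, mi / mc, NA_real_),
      undefined = mc == 0, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bray-Curtis similarity between two samples
#'
#' `1 - sum(|x - y|) / sum(x + y)`; 1 for identical samples, 0 for
#' disjoint ones. Intended for rarefied (equal-total) count vectors.
#'
#' @param x,y non-negative count vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x + y)
  if (tot == 0) stop("both samples are all-zero", call. = FALSE)
  1 - sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix of an OTU table
#'
#' @param table an `amf_otu_table` or samples x OTUs matrix.
#' @return a `dist` of Bray-Curtis dissimilarities (1 - similarity).
#' @export
bray_curtis_dist <- function(table) {
  counts <- if (inherits(table, "amf_otu_table")) table$counts else table
  vegan::vegdist(counts, method = "bray")
}

# Gower-centered inner-product matrix of a distance matrix.
gower_center <- function(D) {
  D <- as.matrix(D)
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Permutational multivariate analysis of variance
#'
#' McArdle-Anderson partitioning of a dissimilarity matrix over a
#' crossed factorial design with sequential (Type I) sums of squares;
#' the default model is `~ trial * inoculated`. Significance comes from
#' free permutation of sample labels:
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)` for sampled
#' permutations, or the exact proportion over a complete enumeration
#' (which includes the identity) when `permutations = "exact"`.
#'
#' @param d a `dist` or symmetric zero-diagonal matrix of
#'   dissimilarities.
#' @param data data.frame of factors, rows aligned with `d`.
#' @param formula right-hand-side model formula over columns of `data`.
#' @param permutations number of random permutations (default 9999), a
#'   permutation matrix (one permutation per row), or `"exact"` for
#'   complete enumeration (n <= 8).
#' @param seed integer seed for sampled permutations.
#' @param blocks optional factor restricting permutations to occur
#'   within its levels.
#' @return data.frame of class `amf_permanova`, one row per term plus
#'   Residual/Total: `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(d, data, formula = ~ trial * inoculated,
                      permutations = 9999, seed = 1, blocks = NULL) {
  D <- as.matrix(d)
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  n <- nrow(D)
  tm <- stats::terms(formula, data = data)
  labels <- attr(tm, "term.labels")
  mf <- stats::model.frame(formula, data)
  for (v in names(mf)) {
    if (!is.numeric(mf[[v]]) && length(unique(mf[[v]])) < 2L)
      stop("factor '", v, "' has a single level", call. = FALSE)
  }
  G <- gower_center(D)
  ss_total <- sum(diag(G))
  # sequential hat matrices
  hat_of <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  X0 <- matrix(1, n, 1)
  hats <- list(hat_of(X0))
  dfs <- integer(length(labels))
  for (j in seq_along(labels)) {
    fj <- stats::reformulate(labels[seq_len(j)])
    Xj <- stats::model.matrix(fj, mf)
    hats[[j + 1L]] <- hat_of(Xj)
    dfs[j] <- qr(Xj)$rank - qr(stats::model.matrix(
      if (j == 1L) ~1 else stats::reformulate(labels[seq_len(j - 1L)]),
      mf))$rank
  }
  H_full <- hats[[length(hats)]]
  df_res <- n - sum(dfs) - 1L
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  I_n <- diag(n)
  # SS of each term and residual for a permuted G
  part <- function(Gp) {
    ss <- vapply(seq_along(labels), function(j)
      sum((hats[[j + 1L]] - hats[[j]]) * Gp), numeric(1))
    c(ss, sum((I_n - H_full) * Gp))
  }
  obs <- part(G)
  F_obs <- (obs[seq_along(labels)] / dfs) / (obs[length(obs)] / df_res)

  if (identical(permutations, "exact")) {
    if (n > 8L) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    exact <- TRUE
  } else if (is.matrix(permutations)) {
    perms <- permutations
    exact <- TRUE  # caller-supplied set: exact proportion convention
  } else {
    n_perm <- as.integer(permutations)
    perms <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) {
        if (is.null(blocks)) sample.int(n)
        else {
          p <- seq_len(n)
          for (b in split(seq_len(n), blocks)) p[b] <- b[sample.int(length(b))]
          p
        }
      }, integer(n)))
    })
    exact <- FALSE
  }
  count_ge <- numeric(length(labels))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    sp <- part(G[p, p])
    Fp <- (sp[seq_along(labels)] / dfs) / (sp[length(sp)] / df_res)
    count_ge <- count_ge + (Fp >= F_obs - 1e-12)
  }
  pval <- if (exact) count_ge / nrow(perms)
          else (1 + count_ge) / (1 + nrow(perms))
  res <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(obs, ss_total),
    R2 = c(obs, ss_total) / ss_total,
    F = c(F_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  class(res) <- c("amf_permanova", "data.frame")
  attr(res, "n_perm") <- nrow(perms)
  res
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Pearson correlation with optional log transforms
#'
#' Zeros are replaced by `pseudo` (default 0.5) before a natural-log
#' transform, keeping the transform monotone on counts.
#'
#' @param x,y numeric vectors.
#' @param log_x,log_y log-transform the respective variable.
#' @param pseudo replacement for zeros under the log transform.
#' @return list: `r`, `p` (two-sided t test), `n`, `estimate` data.
#' @export
correlate <- function(x, y, log_x = FALSE, log_y = FALSE, pseudo = 0.5) {
  tf <- function(v, lg) {
    if (!lg) return(v)
    if (any(v < 0)) stop("log transform needs non-negative data",
                         call. = FALSE)
    log(ifelse(v == 0, pseudo, v))
  }
  x <- tf(x, log_x); y <- tf(y, log_y)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 finite pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Odds ratio of a logistic-regression coefficient
#'
#' @param coefficient coefficient on the log-odds scale.
#' @return `exp(coefficient)`.
#' @export
#' @examples
#' odds_ratio(-8.68)  # ~0.00017
odds_ratio <- function(coefficient) {
  stopifnot(is.finite(coefficient))
  exp(coefficient)
}

#' Multiple linear regression with bidirectional stepwise-AIC selection
#'
#' Fits the full ordinary-least-squares model of `response` on all
#' `candidates`, runs bidirectional stepwise search minimizing AIC from
#' the full model, and reports coefficient estimates, standard errors,
#' p-values, and standardized partial regression coefficients (the
#' slopes of the selected model refit on z-scored response and
#' predictors). If the greedy search ends above the null or full
#' model's AIC, the better of those is returned instead.
#'
#' @param data data.frame holding response and covariates.
#' @param response name of the response column.
#' @param candidates names of candidate covariate columns.
#' @return object of class `amf_lm_fit`: list with `model` (an `lm`),
#'   `selected` (term names), `coefficients` (data.frame: term,
#'   estimate, se, p, std_coef), `aic`.
#' @export
stepwise_lm <- function(data, response, candidates) {
  stopifnot(response %in% names(data), all(candidates %in% names(data)))
  if (nrow(data) <= length(candidates) + 1L)
    stop("need n > number of candidates for the full model", call. = FALSE)
  X <- data[, candidates, drop = FALSE]
  keep <- vapply(candidates, function(v) stats::sd(data[[v]]) > 0,
                 logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(candidates[!keep], collapse = ", "), call. = FALSE)
    candidates <- candidates[keep]
  }
  full <- stats::lm(stats::reformulate(candidates, response), data = data)
  al <- stats::alias(full)
  if (!is.null(al$Complete)) {
    drop <- rownames(al$Complete)
    warning("dropping collinear covariate(s): ",
            paste(drop, collapse = ", "), call. = FALSE)
    candidates <- setdiff(candidates, drop)
    full <- stats::lm(stats::reformulate(candidates, response), data = data)
  }
  null <- stats::lm(stats::reformulate("1", response), data = data)
  sel <- stats::step(full, scope = list(lower = ~1,
                                        upper = stats::formula(full)),
                     direction = "both", trace = 0)
  fits <- list(sel, full, null)
  best <- fits[[which.min(vapply(fits, stats::AIC, numeric(1)))]]
  terms_sel <- attr(stats::terms(best), "term.labels")
  cf <- summary(best)$coefficients
  std <- rep(NA_real_, nrow(cf))
  if (length(terms_sel)) {
    zd <- data
    for (v in c(response, terms_sel)) zd[[v]] <- as.numeric(scale(zd[[v]]))
    zfit <- stats::lm(stats::reformulate(terms_sel, response), data = zd)
    std[match(terms_sel, rownames(cf))] <-
      stats::coef(zfit)[terms_sel]
  }
  structure(list(
    model = best, selected = terms_sel,
    coefficients = data.frame(
      term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
      p = cf[, 4], std_coef = std, row.names = NULL,
      stringsAsFactors = FALSE),
    aic = stats::AIC(best)), class = "amf_lm_fit")
}

#' @export
print.amf_lm_fit <- function(x, ...) {
  cat("Stepwise OLS fit (AIC ", round(x$aic, 2), "), selected terms: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Binomial logistic regression with a random block intercept
#'
#' Models per-plot inoculum read counts out of the rarefaction depth as
#' a binomial logit GLMM with a Gaussian random intercept per block,
#' fitted by adaptive Gauss-Hermite quadrature (lme4). With
#' `re_variance = "zero"` the random effect is fixed at zero variance
#' and the model reduces to a plain binomial GLM. Optional all-subsets
#' AIC selection over the candidate covariates. Odds ratios are
#' `exp(coefficient)`.
#'
#' @param data data.frame with covariates and a block column.
#' @param successes,trials column names of the success and trial counts
#'   (e.g. tracked reads and rarefaction depth).
#' @param candidates candidate covariate column names.
#' @param block name of the blocking factor column.
#' @param select `"none"` (fit all candidates) or `"aic"` (all-subsets
#'   search minimizing AIC).
#' @param nagq quadrature points for the adaptive Gauss-Hermite
#'   approximation.
#' @param re_variance `"estimate"` or `"zero"`.
#' @param standardize z-score the covariates before fitting (helps the
#'   optimizer when covariates live on very different scales);
#'   coefficients are then per standard deviation of the covariate.
#' @return object of class `amf_glmm_fit`: `model`, `coefficients`
#'   (term, estimate, se, p, odds_ratio), `aic`, `re_sd`, `selected`,
#'   `converged`.
#' @export
logistic_glmm <- function(data, successes, trials, candidates, block,
                          select = c("none", "aic"), nagq = 8L,
                          re_variance = c("estimate", "zero"),
                          standardize = FALSE) {
  select <- match.arg(select)
  re_variance <- match.arg(re_variance)
  stopifnot(all(c(successes, trials, block, candidates) %in% names(data)))
  s <- data[[successes]]; t_ <- data[[trials]]
  if (any(s > t_)) stop("successes exceed trials", call. = FALSE)
  if (standardize)
    for (v in candidates)
      if (stats::sd(data[[v]]) > 0)
        data[[v]] <- as.numeric(scale(data[[v]]))
  fit_one <- function(covs) {
    rhs <- if (length(covs)) paste(covs, collapse = " + ") else "1"
    if (re_variance == "zero") {
      f <- stats::as.formula(paste0("cbind(", successes, ", ", trials,
                                    " - ", successes, ") ~ ", rhs))
      stats::glm(f, family = stats::binomial(), data = data)
    } else {
      f <- stats::as.formula(paste0("cbind(", successes, ", ", trials,
                                    " - ", successes, ") ~ ", rhs,
                                    " + (1 | ", block, ")"))
      lme4::glmer(f, family = stats::binomial(), data = data, nAGQ = nagq)
    }
  }
  if (select == "aic") {
    subsets <- unlist(lapply(0:length(candidates), function(k)
      utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
    fits <- lapply(subsets, function(cv)
      tryCatch(fit_one(cv), error = function(e) NULL))
    aics <- vapply(fits, function(f)
      if (is.null(f)) Inf else stats::AIC(f), numeric(1))
    best_i <- which.min(aics)
    model <- fits[[best_i]]
    selected <- subsets[[best_i]]
  } else {
    model <- fit_one(candidates)
    selected <- candidates
  }
  is_glmm <- inherits(model, "merMod")
  cf <- if (is_glmm) stats::coef(summary(model))
        else summary(model)$coefficients
  converged <- TRUE
  if (is_glmm) {
    msgs <- model@optinfo$conv$lme4$messages
    # a singular (zero-variance) random effect is a boundary estimate,
    # not a convergence failure
    msgs <- msgs[!grepl("singular", msgs)]
    if (length(msgs)) {
      converged <- FALSE
      grad <- tryCatch(
        sqrt(sum(model@optinfo$derivs$gradient^2)), error = function(e) NA)
      warning("GLMM convergence issue (gradient norm ",
              format(grad, digits = 3), "): ",
              paste(msgs, collapse = "; "), call. = FALSE)
    }
  }
  structure(list(
    model = model, selected = selected,
    coefficients = data.frame(
      term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
      p = cf[, 4], odds_ratio = exp(cf[, 1]), row.names = NULL,
      stringsAsFactors = FALSE),
    aic = stats::AIC(model),
    re_sd = if (is_glmm)
      sqrt(lme4::VarCorr(model)[[1]][1, 1]) else 0,
    converged = converged), class = "amf_glmm_fit")
}

#' @export
print.amf_glmm_fit <- function(x, ...) {
  cat("Binomial logistic ", if (x$re_sd > 0 || inherits(x$model, "merMod"))
    "GLMM (random block intercept)" else "GLM",
    ", AIC ", round(x$aic, 2),
    ", random-intercept s.d. ", format(x$re_sd, digits = 3), "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}
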