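.sex_suffix <- c(male = "M", female = "F")

#' Fit sex-specific principal components by singular value decomposition
#'
#' For each sex, the corresponding rows of the design matrix are column
#' centered and factorized as \eqn{X = U S V^\top}; the loadings are the
#' right singular vectors. Components are named `PC1M, PC2M, ...` for males
#' and `PC1F, ...` for females. The sign of each loading column is fixed so
#' that its largest-magnitude entry is positive (SVD signs are arbitrary;
#' a fixed convention makes loading interpretation reproducible). Training
#' column means are stored so new subjects project consistently.
#'
#' @param design A [normalize_cohort()] design matrix.
#' @return An object of class `"factor_model"`: per sex a list with
#'   elements `center`, `loadings` (parameters x components, orthonormal
#'   columns), `d` (singular values, non-increasing) and `components`;
#'   plus top-level `params` and `selected` (initially all components).
#' @export
fit_factor_model <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  sex <- attr(design, "sex")
  params <- attr(design, "params")
  out <- list(params = params, by_sex = list(), selected = character())
  for (s in intersect(c("male", "female"), unique(sex))) {
    X <- design[sex == s, , drop = FALSE]
    if (nrow(X) < 2L || ncol(X) < 2L) {
      stop("need at least 2 rows and 2 columns for sex '", s, "'")
    }
    center <- colMeans(X)
    Xc <- sweep(X, 2L, center)
    if (all(abs(Xc) < 1e-12)) stop("design matrix has rank 0 for sex '", s, "'")
    sv <- svd(Xc)
    V <- sv$v
    # sign convention: largest-magnitude loading entry positive
    flip <- apply(V, 2L, function(v) sign(v[which.max(abs(v))]))
    V <- sweep(V, 2L, flip, `*`)
    comps <- paste0("PC", seq_len(ncol(V)), .sex_suffix[[s]])
    dimnames(V) <- list(params, comps)
    out$by_sex[[s]] <- list(center = center, loadings = V, d = sv$d,
                            components = comps, n = nrow(X))
    out$selected <- c(out$selected, comps)
  }
  class(out) <- "factor_model"
  out
}

#' Project subjects onto the stored loadings
#'
#' Each subject's centered z-vector is projected onto the loadings of the
#' model fit for their own sex; scoring a subject against the other sex's
#' model is an error, not a silent misuse. Returns scores for all
#' components (selection is applied downstream).
#'
#' @param design A [normalize_cohort()] design matrix.
#' @param model A [fit_factor_model()] result.
#' @param selected_only Restrict columns to `model$selected`.
#' @return A `data.frame` with columns `id`, `sex`, then one column per
#'   component; components of the other sex are `NA` in a subject's row.
#' @export
project_scores <- function(design, model, selected_only = FALSE) {
  stopifnot(inherits(design, "design_matrix"), inherits(model, "factor_model"))
  sex <- attr(design, "sex")
  params <- attr(design, "params")
  missing_sex <- setdiff(unique(sex), names(model$by_sex))
  if (length(missing_sex) > 0L) {
    stop("factor model has no components for sex: ",
         paste(missing_sex, collapse = ", "))
  }
  if (!identical(params, model$params)) {
    extra <- setdiff(params, model$params)
    lack <- setdiff(model$params, params)
    stop("parameter mismatch between design matrix and factor model",
         if (length(lack)) paste0("; missing: ", paste(lack, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
         if (!length(lack) && !length(extra)) "; order differs")
  }
  all_comps <- unlist(lapply(model$by_sex, `[[`, "components"),
                      use.names = FALSE)
  if (selected_only) all_comps <- intersect(all_comps, model$selected)
  scores <- matrix(NA_real_, nrow(design), length(all_comps),
                   dimnames = list(rownames(design), all_comps))
  for (s in names(model$by_sex)) {
    rows <- sex == s
    if (!any(rows)) next
    m <- model$by_sex[[s]]
    keep <- intersect(m$components, all_comps)
    pr <- sweep(design[rows, , drop = FALSE], 2L, m$center) %*%
      m$loadings[, keep, drop = FALSE]
    scores[rows, keep] <- pr
  }
  data.frame(id = rownames(design), sex = sex, scores,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Select the component subset used by the clock
#'
#' Sets `model$selected` according to a policy, per sex:
#' \describe{
#'   \item{`"mortality_fdr"` (default)}{retain components individually
#'     associated with all-cause mortality in a univariate Cox model at
#'     Benjamini-Hochberg FDR < `fdr`. Mortality association matches the
#'     clock's training target.}
#'   \item{`"all"`}{every component.}
#'   \item{`"top_k"`}{the `k` highest-variance components per sex.}
#'   \item{`"age_cor"`}{components with |Pearson r| with chronological age
#'     >= `r_min`.}
#' }
#'
#' @param model A [fit_factor_model()] result.
#' @param scores A [project_scores()] table.
#' @param cohort The cohort the scores came from (survival fields aligned
#'   by `id`).
#' @param policy Selection policy.
#' @param fdr BH FDR threshold for `"mortality_fdr"`.
#' @param k Number of components for `"top_k"`.
#' @param r_min Age-correlation threshold for `"age_cor"`.
#' @return The model with `selected` set and the per-component statistics
#'   in attribute `"selection_table"`.
#' @export
select_components <- function(model, scores, cohort,
                              policy = c("mortality_fdr", "all", "top_k",
                                         "age_cor"),
                              fdr = 0.05, k = 10, r_min = 0.3) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "factor_model"))
  if (policy == "all") {
    model$selected <- unlist(lapply(model$by_sex, `[[`, "components"),
                             use.names = FALSE)
    attr(model, "selection_table") <- NULL
    return(model)
  }
  if (policy == "top_k") {
    sel <- unlist(lapply(model$by_sex, function(m)
      m$components[seq_len(min(k, length(m$components)))]), use.names = FALSE)
    model$selected <- sel
    return(model)
  }
  idx <- match(scores$id, cohort$id)
  if (anyNA(idx)) stop("scores contain ids absent from the cohort")
  coh <- cohort[idx, , drop = FALSE]
  tabs <- list()
  selected <- character()
  for (s in names(model$by_sex)) {
    comps <- model$by_sex[[s]]$components
    rows <- scores$sex == s
    if (policy == "age_cor") {
      r <- vapply(comps, function(cp)
        stats::cor(scores[[cp]][rows], coh$chron_age[rows]), numeric(1))
      tab <- data.frame(component = comps, sex = s, statistic = r,
                        p = NA_real_, q = NA_real_,
                        keep = abs(r) >= r_min, stringsAsFactors = FALSE)
    } else { # mortality_fdr
      surv <- survival::Surv(coh$follow_up_time[rows],
                             coh$event[rows] == "died")
      stat <- p <- rep(NA_real_, length(comps))
      for (i in seq_along(comps)) {
        fit <- survival::coxph(surv ~ x,
                               data = data.frame(x = scores[[comps[i]]][rows]),
                               ties = "efron")
        sm <- summary(fit)$coefficients
        stat[i] <- sm[1, "z"]
        p[i] <- sm[1, "Pr(>|z|)"]
      }
      q <- stats::p.adjust(p, method = "BH")
      tab <- data.frame(component = comps, sex = s, statistic = stat,
                        p = p, q = q, keep = q < fdr,
                        stringsAsFactors = FALSE)
    }
    tabs[[s]] <- tab
    selected <- c(selected, comps[tab$keep])
  }
  if (length(selected) == 0L) {
    stop("no component passes the '", policy,
         "' selection policy; consider relaxing it (e.g. policy = 'top_k')")
  }
  model$selected <- selected
  attr(model, "selection_table") <- do.call(rbind, tabs)
  model
}
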