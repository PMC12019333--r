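.num_fmt <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  df
}

.write_table <- function(df, path) {
  utils::write.csv(.num_fmt(df), path, row.names = FALSE, na = "")
}

#' Serialize / load a trained clock bundle
#'
#' A clock bundle is a directory of plain comma-separated tables plus a
#' small JSON metadata file, mirroring how published clock coefficients
#' are distributed in supplementary tables so published coefficients can
#' be dropped in verbatim:
#' \describe{
#'   \item{`parameters.csv`}{the parameter manifest (name, transform,
#'     units, required).}
#'   \item{`reference_stats.csv`}{per-sex medians and raw MADs.}
#'   \item{`loadings_male.csv` / `loadings_female.csv`}{parameters x
#'     components.}
#'   \item{`factor_meta.csv`}{per component: sex, singular value,
#'     selected flag.}
#'   \item{`centers.csv`}{per-sex training column means.}
#'   \item{`cox_weights.csv`}{sex, component, beta, se, z, p.}
#'   \item{`metadata.json`}{gamma, MRDT, centering coefficients,
#'     MAD constant, cap, score scale ("raw" PC scores), versions,
#'     training provenance.}
#' }
#' Numerics are written with 17 significant digits, so a round trip is
#' lossless for doubles. `read_bundle` checks referential integrity (every
#' weighted component must exist in the loadings) and the format version.
#'
#' @param clock A `"pcclock"` object.
#' @param path Bundle directory (created if needed).
#' @return `write_bundle` returns `path` invisibly; `read_bundle` returns
#'   a `"pcclock"` object ready for [predict.pcclock()].
#' @export
write_bundle <- function(clock, path) {
  stopifnot(inherits(clock, "pcclock"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  .write_table(as.data.frame(clock$spec), file.path(path, "parameters.csv"))
  ref <- as.data.frame(clock$reference)
  .write_table(ref, file.path(path, "reference_stats.csv"))
  fm <- clock$factor_model
  meta_rows <- list()
  centers <- list()
  for (s in names(fm$by_sex)) {
    m <- fm$by_sex[[s]]
    L <- data.frame(parameter = rownames(m$loadings), m$loadings,
                    check.names = FALSE, stringsAsFactors = FALSE)
    .write_table(L, file.path(path, paste0("loadings_", s, ".csv")))
    meta_rows[[s]] <- data.frame(
      sex = s, component = m$components, singular_value = m$d,
      selected = m$components %in% fm$selected, stringsAsFactors = FALSE)
    centers[[s]] <- data.frame(sex = s, parameter = names(m$center),
                               mean = unname(m$center),
                               stringsAsFactors = FALSE)
  }
  .write_table(do.call(rbind, meta_rows), file.path(path, "factor_meta.csv"))
  .write_table(do.call(rbind, centers), file.path(path, "centers.csv"))
  w <- do.call(rbind, lapply(names(clock$weights), function(s)
    cbind(sex = s, clock$weights[[s]])))
  .write_table(w, file.path(path, "cox_weights.csv"))
  # doubles are stored as 17-significant-digit strings: JSON writers
  # truncate to 15 digits, which would break lossless round-tripping
  num <- function(x) sprintf("%.17g", x)
  meta <- list(
    format_version = 1L,
    gamma = num(clock$gamma), gamma_se = num(clock$gamma_se),
    mrdt = num(clock$mrdt),
    centering_type = clock$centering_type,
    centering = lapply(clock$centering, function(ab)
      list(a = num(ab[["a"]]), b = num(ab[["b"]]))),
    mad_constant = attr(clock$reference, "mad_constant"),
    age_window = attr(clock$reference, "age_window"),
    cap = clock$cap, max_missing = clock$max_missing,
    include_ca = clock$include_ca, score_scale = clock$score_scale,
    training = list(n = clock$training$n, events = clock$training$events,
                    version = clock$training$version)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  need <- c("parameters.csv", "reference_stats.csv", "factor_meta.csv",
            "centers.csv", "cox_weights.csv", "metadata.json")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss) > 0L) {
    stop("bundle at '", path, "' is missing component table(s): ",
         paste(miss, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L) {
    stop("unsupported bundle format version: ", meta$format_version)
  }
  rd <- function(f) utils::read.csv(file.path(path, f),
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE, na.strings = "")
  spec_df <- rd("parameters.csv")
  spec <- parameter_spec(spec_df$name, spec_df$transform, spec_df$units,
                         spec_df$required)
  ref <- rd("reference_stats.csv")
  fmeta <- rd("factor_meta.csv")
  centers <- rd("centers.csv")
  wt <- rd("cox_weights.csv")
  params <- spec$name
  ref <- structure(ref, mad_constant = meta$mad_constant,
                   age_window = meta$age_window, dropped = character(),
                   params = params, spec = spec,
                   class = c("reference_stats", "data.frame"))
  fm <- list(params = params, by_sex = list(), selected = character())
  for (s in unique(fmeta$sex)) {
    lf <- file.path(path, paste0("loadings_", s, ".csv"))
    if (!file.exists(lf)) stop("bundle missing loadings table for sex ", s)
    L <- rd(paste0("loadings_", s, ".csv"))
    comps <- fmeta$component[fmeta$sex == s]
    bad <- setdiff(comps, names(L))
    if (length(bad) > 0L) {
      stop("factor_meta lists component(s) absent from loadings_", s,
           ".csv: ", paste(bad, collapse = ", "))
    }
    Lm <- as.matrix(L[, comps, drop = FALSE])
    rownames(Lm) <- L$parameter
    Lm <- Lm[params, , drop = FALSE]
    cen <- centers[centers$sex == s, , drop = FALSE]
    fm$by_sex[[s]] <- list(
      center = stats::setNames(cen$mean, cen$parameter)[params],
      loadings = Lm, d = fmeta$singular_value[fmeta$sex == s],
      components = comps, n = NA_integer_)
    fm$selected <- c(fm$selected,
                     comps[fmeta$selected[fmeta$sex == s] %in% TRUE])
  }
  class(fm) <- "factor_model"
  weights <- list()
  for (s in unique(wt$sex)) {
    w <- wt[wt$sex == s, setdiff(names(wt), "sex"), drop = FALSE]
    rownames(w) <- NULL
    known <- c(fm$by_sex[[s]]$components, "chron_age")
    bad <- setdiff(w$component, known)
    if (length(bad) > 0L) {
      stop("cox_weights references component(s) absent from the ", s,
           " loadings: ", paste(bad, collapse = ", "))
    }
    weights[[s]] <- w
  }
  obj <- list(
    spec = spec, reference = ref, factor_model = fm, weights = weights,
    gamma = as.numeric(meta$gamma), gamma_se = as.numeric(meta$gamma_se),
    mrdt = as.numeric(meta$mrdt),
    centering = lapply(meta$centering, function(ab)
      c(a = as.numeric(ab$a), b = as.numeric(ab$b))),
    centering_type = meta$centering_type,
    include_ca = isTRUE(meta$include_ca), cap = meta$cap,
    max_missing = meta$max_missing, score_scale = meta$score_scale,
    training = list(n = meta$training$n, events = meta$training$events,
                    version = meta$training$version)
  )
  class(obj) <- "pcclock"
  obj
}
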