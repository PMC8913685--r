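#' @keywords internal
#' Reshape a seasonal climate table to one row per site-year
#'
#' Produces columns `tmax_pSUM`, ..., `pp_AUT` matching the model vocabulary.
#' @noRd
.seasonal_wide <- function(seasonal, seasons = SEASONS,
                           climate_vars = CLIMATE_VARS) {
  key <- paste(seasonal$site_id, seasonal$year, sep = "\r")
  ukey <- unique(key)
  out <- data.frame(site_id = seasonal$site_id[match(ukey, key)],
                    year = seasonal$year[match(ukey, key)])
  src <- c(tmax = "tmax_mean", tmin = "tmin_mean", pp = "pp_sum")
  for (v in climate_vars) for (s in seasons) {
    sel <- seasonal$season == s
    col <- rep(NA_real_, length(ukey))
    col[match(key[sel], ukey)] <- seasonal[[src[[v]]]][sel]
    out[[paste(v, s, sep = "_")]] <- col
  }
  out
}

# variable-level transform (log where declared) + z-standardization;
# returns list(z = named list of vectors, var_stats = data.frame)
.var_transform <- function(base, spec, scaler = NULL, ba_ref = NULL) {
  vars <- spec$variables
  names_all <- vars$name
  has_ba <- "ba_prev" %in% names(base)
  if (has_ba) names_all <- c(names_all, "ba_prev")
  stats <- data.frame(name = names_all, mean = NA_real_, sd = NA_real_,
                      stringsAsFactors = FALSE)
  z <- list()
  for (i in seq_along(names_all)) {
    v <- names_all[i]
    x <- base[[v]]
    if (is.null(x)) stop("design: variable '", v, "' missing from input data")
    if (anyNA(x)) stop("design: variable '", v, "' contains missing values")
    tr <- if (v == "ba_prev") "none" else vars$transform[vars$name == v]
    if (tr == "log") {
      off <- if (grepl("^pp_", v)) spec$pp_offset else 0
      if (any(x + off <= 0))
        stop("design: log transform of '", v, "' undefined (values <= ",
             -off, "); configure a positive pp_offset" )
      x <- log(x + off)
    }
    if (!is.null(scaler)) {
      j <- match(v, scaler$var$name)
      if (is.na(j)) stop("design: variable '", v, "' not in the stored scaler")
      m <- scaler$var$mean[j]; s <- scaler$var$sd[j]
    } else if (v == "ba_prev" && !is.null(ba_ref)) {
      m <- ba_ref[["mean"]]; s <- ba_ref[["sd"]]
    } else {
      m <- mean(x); s <- sd(x)
      if (!is.finite(s) || s < 1e-12)
        stop("design: variable '", v, "' is constant (zero SD); cannot standardize")
    }
    z[[v]] <- (x - m) / s
    stats$mean[i] <- m; stats$sd[i] <- s
  }
  list(z = z, var_stats = stats)
}

# expand z-scored variables into basis columns and interaction products,
# then standardize every final column; returns list(X, col_stats)
.expand_and_scale <- function(z, spec, scaler = NULL, pin_identity = character(0)) {
  cols <- design_columns(spec)
  n <- length(z[[1]])
  raw <- matrix(NA_real_, n, nrow(cols), dimnames = list(NULL, cols$name))
  base_col <- function(nm) {
    # nm is either a variable name, var_k for basis column k, or a.x.b product
    if (!is.null(z[[nm]])) return(z[[nm]])
    mm <- regmatches(nm, regexec("^(.*)_([12])$", nm))[[1]]
    if (length(mm) == 3L && !is.null(z[[mm[2]]]))
      return(z[[mm[2]]]^as.integer(mm[3]))
    stop("design: cannot resolve column '", nm, "'")
  }
  for (j in seq_len(nrow(cols))) {
    nm <- cols$name[j]
    if (cols$kind[j] == "interaction") {
      ab <- strsplit(nm, ".x.", fixed = TRUE)[[1]]
      raw[, j] <- base_col(ab[1]) * base_col(ab[2])
    } else raw[, j] <- base_col(nm)
  }
  stats <- data.frame(name = cols$name, mean = NA_real_, sd = NA_real_,
                      stringsAsFactors = FALSE)
  for (j in seq_len(nrow(cols))) {
    nm <- cols$name[j]
    if (!is.null(scaler)) {
      k <- match(nm, scaler$col$name)
      if (is.na(k)) stop("design: column '", nm, "' not in the stored scaler")
      m <- scaler$col$mean[k]; s <- scaler$col$sd[k]
    } else if (nm %in% pin_identity) {
      m <- 0; s <- 1
    } else {
      m <- mean(raw[, j]); s <- sd(raw[, j])
      if (!is.finite(s) || s < 1e-12)
        stop("design: design column '", nm, "' is constant (zero SD)")
    }
    raw[, j] <- (raw[, j] - m) / s
    stats$mean[j] <- m; stats$sd[j] <- s
  }
  list(X = raw, col_stats = stats)
}

# full design-matrix construction from a base table holding the vocabulary
# variables (+ ba_prev). Returns X, the ba z-score (for the random slope),
# the scaler and column metadata.
.design_matrix <- function(base, spec, scaler = NULL, ba_ref = NULL) {
  vt <- .var_transform(base, spec, scaler = scaler, ba_ref = ba_ref)
  pin <- if (is.null(scaler) && !is.null(ba_ref)) "ba_prev" else character(0)
  es <- .expand_and_scale(vt$z, spec, scaler = scaler, pin_identity = pin)
  list(X = es$X,
       ba_z = if ("ba_prev" %in% names(vt$z)) vt$z[["ba_prev"]] else NULL,
       scaler = scaler %||% list(var = vt$var_stats, col = es$col_stats),
       col_info = design_columns(spec))
}

#' Build the standardized growth-model design
#'
#' Joins the BAI table with the wide seasonal climate table and site
#' metadata, then constructs the fixed-effect design: log transforms
#' (aridity index, seasonal precipitation with offset), per-variable
#' z-standardization, polynomial basis expansion of the smoothed variables,
#' interaction products, and a final z-standardization of every design
#' column. The standardization constants (the *scaler*) are stored on the
#' design for reuse at prediction time.
#'
#' When `scaler` is supplied (e.g. the scaler a simulation was generated
#' under), its constants are used instead of sample statistics, so fitted
#' coefficients live on exactly the scale of the generating parameters.
#'
#' @param bai_table A `bai_table` from [rings_to_bai()].
#' @param seasonal A `seasonal_climate` table from [aggregate_seasons()].
#' @param sites Data.frame with `site_id`, `lat`, `alt`, `ai`.
#' @param spec A [model_spec()].
#' @param scaler Optional stored scaler (list with `var` and `col` tables).
#' @param ba_ref Optional `c(mean, sd)` pinning the standardization of
#'   previous-year basal area (used when fitting data simulated under a
#'   reference scale).
#' @return An object of class `growth_design`: response, design matrix,
#'   grouping factor, `ba_z` random-slope covariate, scaler, column info.
#' @export
build_design <- function(bai_table, seasonal, sites, spec = model_spec(),
                         scaler = NULL, ba_ref = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("site_id", "lat", "alt", "ai")
  if (!all(need %in% names(sites)))
    stop("build_design: sites table needs columns ", paste(need, collapse = ", "))
  if (any(bai_table$bai <= 0))
    stop("build_design: BAI must be strictly positive for the gamma response")
  wide <- .seasonal_wide(seasonal, spec$seasons, spec$climate_vars)
  idx <- match(paste(bai_table$site_id, bai_table$year),
               paste(wide$site_id, wide$year))
  if (anyNA(idx)) {
    miss <- unique(paste(bai_table$site_id, bai_table$year)[is.na(idx)])
    stop("build_design: no seasonal climate for ", length(miss),
         " site-year(s), e.g. ", paste(head(miss, 3), collapse = "; "))
  }
  sidx <- match(bai_table$site_id, sites$site_id)
  if (anyNA(sidx))
    stop("build_design: sites missing from the site table: ",
         paste(unique(bai_table$site_id[is.na(sidx)]), collapse = ", "))
  clim_cols <- setdiff(names(wide), c("site_id", "year"))
  base <- cbind(
    data.frame(ai = sites$ai[sidx], lat = sites$lat[sidx],
               alt = sites$alt[sidx], ba_prev = bai_table$ba_prev),
    wide[idx, clim_cols, drop = FALSE])
  bad <- clim_cols[vapply(wide[idx, clim_cols, drop = FALSE], anyNA, logical(1))]
  if (length(bad))
    stop("build_design: incomplete seasonal climate for the model rows in: ",
         paste(bad, collapse = ", "))
  dm <- .design_matrix(base, spec, scaler = scaler, ba_ref = ba_ref)
  structure(
    list(y = bai_table$bai,
         X = dm$X,
         tree = factor(paste(bai_table$site_id, bai_table$tree_code, sep = "/")),
         ba_z = dm$ba_z,
         site_id = bai_table$site_id,
         year = bai_table$year,
         col_info = dm$col_info,
         scaler = dm$scaler,
         spec = spec),
    class = "growth_design")
}

#' @export
print.growth_design <- function(x, ...) {
  cat(sprintf("<growth_design> %d obs, %d trees, %d fixed-effect columns (%d main variables)\n",
              length(x$y), nlevels(x$tree), ncol(x$X), n_main_variables(x$spec)))
  invisible(x)
}
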