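#' Specification of the growth-model design
#'
#' Declares the variable vocabulary and structure of the continental growth
#' model: the long-term aridity index (log-transformed), latitude and
#' altitude (smooth terms), seasonal maximum/minimum temperature (smooth
#' terms) and seasonal precipitation (log-transformed) for the six seasons
#' from previous-year summer to current-year autumn, the interaction blocks,
#' and the per-tree random structure (correlated random intercept and random
#' slope on previous-year basal area). The response family is gamma with a
#' log link throughout.
#'
#' With the default six seasons and three climate variables the vocabulary
#' holds exactly 21 main variables (18 seasonal + aridity + latitude +
#' altitude).
#'
#' @param seasons Character vector of season labels to use (subset of
#'   `pSUM, pAUT, WIN, SPR, SUM, AUT`). The default uses all six.
#' @param climate_vars Climate variables, subset of `tmax`, `tmin`, `pp`.
#' @param smooth_df Degrees of freedom of the polynomial smooth applied to
#'   latitude, altitude and temperature variables (1 = linear, 2 = quadratic).
#' @param interactions Character vector of interaction blocks to include:
#'   `"ai_geo"` (aridity x latitude, aridity x altitude), `"geo_geo"`
#'   (latitude x altitude), `"ai_cli"`, `"lat_cli"`, `"alt_cli"` (each the
#'   named variable crossed with every seasonal climate term). Use
#'   `character(0)` for a main-effects model.
#' @param pp_offset Additive offset (mm) applied inside `log(pp + offset)`
#'   to guard zero seasonal precipitation.
#' @param ba_fixed Logical; include standardized previous-year basal area as
#'   a fixed-effect column (the deterministic companion of its random slope).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(seasons = SEASONS,
                       climate_vars = CLIMATE_VARS,
                       smooth_df = 2L,
                       interactions = c("ai_geo", "geo_geo", "ai_cli",
                                        "lat_cli", "alt_cli"),
                       pp_offset = 1,
                       ba_fixed = TRUE) {
  stopifnot(all(seasons %in% SEASONS), all(climate_vars %in% CLIMATE_VARS),
            smooth_df %in% c(1L, 2L))
  known_blocks <- c("ai_geo", "geo_geo", "ai_cli", "lat_cli", "alt_cli")
  if (!all(interactions %in% known_blocks))
    stop("model_spec: unknown interaction block(s): ",
         paste(setdiff(interactions, known_blocks), collapse = ", "))
  cli_vars <- as.vector(outer(climate_vars, seasons, paste, sep = "_"))
  vars <- data.frame(
    name = c("ai", "lat", "alt", cli_vars),
    group = c("ai", "geo", "geo",
              rep("cli", length(cli_vars))),
    transform = c("log", "none", "none",
                  ifelse(grepl("^pp_", cli_vars), "log", "none")),
    smooth = c(FALSE, TRUE, TRUE, !grepl("^pp_", cli_vars)),
    stringsAsFactors = FALSE)
  structure(
    list(variables = vars, seasons = seasons, climate_vars = climate_vars,
         smooth_df = as.integer(smooth_df), interactions = interactions,
         pp_offset = pp_offset, ba_fixed = isTRUE(ba_fixed),
         family = "Gamma", link = "log"),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %d main variables (%d seasonal x %d climate vars + ai + lat + alt)\n",
    nrow(x$variables), length(x$seasons), length(x$climate_vars)))
  cat(sprintf("  smooth df: %d | interactions: %s | pp offset: %g mm | ba fixed: %s\n",
              x$smooth_df,
              if (length(x$interactions)) paste(x$interactions, collapse = ", ") else "none",
              x$pp_offset, x$ba_fixed))
  cat("  family: gamma(log), random: (1 + ba_prev | tree)\n")
  invisible(x)
}

#' Number of main (pre-expansion) variables of a model spec
#' @param spec A [model_spec()].
#' @return Integer count (21 for the canonical spec).
#' @export
n_main_variables <- function(spec) nrow(spec$variables)

# expanded fixed-effect column names of one variable
.expand_names <- function(spec, var) {
  row <- spec$variables[spec$variables$name == var, ]
  if (nrow(row) == 1L && row$smooth && spec$smooth_df > 1L)
    paste(var, seq_len(spec$smooth_df), sep = "_")
  else var
}

# the interaction pairs implied by the spec's blocks, as a data.frame of
# (var_a, var_b, block)
.interaction_pairs <- function(spec) {
  cli <- spec$variables$name[spec$variables$group == "cli"]
  out <- list()
  add <- function(a, b, blk) out[[length(out) + 1L]] <<- data.frame(
    var_a = a, var_b = b, block = blk, stringsAsFactors = FALSE)
  if ("ai_geo" %in% spec$interactions) { add("ai", "lat", "ai_geo"); add("ai", "alt", "ai_geo") }
  if ("geo_geo" %in% spec$interactions) add("lat", "alt", "geo_geo")
  if ("ai_cli" %in% spec$interactions) for (v in cli) add("ai", v, "ai_cli")
  if ("lat_cli" %in% spec$interactions) for (v in cli) add("lat", v, "lat_cli")
  if ("alt_cli" %in% spec$interactions) for (v in cli) add("alt", v, "alt_cli")
  if (length(out) == 0L) return(data.frame(var_a = character(0),
                                           var_b = character(0),
                                           block = character(0)))
  do.call(rbind, out)
}

#' Enumerate the fixed-effect columns implied by a model spec
#'
#' Returns one row per fixed-effect design column (excluding the intercept):
#' expanded main-effect columns, the lagged-basal-area column if present,
#' and every interaction product column, each tagged with the variable
#' groups it involves.
#'
#' @param spec A [model_spec()].
#' @return Data.frame with columns `name`, `kind` (`main`/`ba`/`interaction`),
#'   `block` and `groups` (comma-joined variable groups, used by the model
#'   ladder to switch blocks off).
#' @export
design_columns <- function(spec) {
  vars <- spec$variables
  rows <- list()
  for (i in seq_len(nrow(vars))) {
    for (nm in .expand_names(spec, vars$name[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, kind = "main", block = vars$group[i],
        groups = vars$group[i], stringsAsFactors = FALSE)
  }
  if (spec$ba_fixed)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "ba_prev", kind = "ba", block = "ba", groups = "",
      stringsAsFactors = FALSE)
  pairs <- .interaction_pairs(spec)
  grp <- setNames(vars$group, vars$name)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$var_a[i]; b <- pairs$var_b[i]
    for (na in .expand_names(spec, a)) for (nb in .expand_names(spec, b))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(na, nb, sep = ".x."), kind = "interaction",
        block = pairs$block[i],
        groups = paste(sort(unique(c(grp[[a]], grp[[b]]))), collapse = ","),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground-truth parameters for forward simulation of the growth model
#'
#' Bundles everything needed to simulate annual growth from the model:
#' the intercept on the log-BAI scale, fixed-effect coefficients on the
#' standardized design scale, the per-tree random-effect distribution,
#' and the gamma shape (dispersion) of the response. Coefficients are given
#' per variable (`coef_main`, a named list of vectors, one entry per expanded
#' basis column) and per interaction pair (`coef_interaction`, named
#' `"var_a:var_b"`). Unnamed design columns default to zero.
#'
#' `ba_ref` fixes the standardization (mean, sd in mm^2) of previous-year
#' basal area used during simulation; freezing it makes the truth
#' well-defined before any data exist.
#'
#' @param spec A [model_spec()] giving the vocabulary.
#' @param intercept Intercept on the log-BAI (mm^2/yr) scale.
#' @param coef_main Named list: variable name -> coefficient vector.
#' @param coef_interaction Named list: `"a:b"` -> coefficient vector over
#'   that pair's product columns (row-major over `a`'s then `b`'s basis).
#' @param re_sd_intercept,re_sd_slope Per-tree random-effect SDs.
#' @param re_corr Intercept-slope correlation, in `[-1, 1]`.
#' @param gamma_shape Gamma shape parameter (> 0); the response variance is
#'   `mu^2 / gamma_shape`.
#' @param ba_ref Numeric `c(mean, sd)` reference standardization of
#'   previous-year basal area, mm^2.
#' @return An object of class `true_params`.
#' @export
true_params <- function(spec,
                        intercept = log(800),
                        coef_main = list(),
                        coef_interaction = list(),
                        re_sd_intercept = 0.25,
                        re_sd_slope = 0.10,
                        re_corr = 0.2,
                        gamma_shape = 8,
                        ba_ref = c(20000, 15000)) {
  stopifnot(inherits(spec, "model_spec"))
  if (gamma_shape <= 0) stop("true_params: gamma_shape must be > 0")
  if (abs(re_corr) > 1) stop("true_params: |re_corr| must be <= 1")
  if (re_sd_intercept < 0 || re_sd_slope < 0)
    stop("true_params: random-effect SDs must be >= 0")
  vocab <- c(spec$variables$name, "ba_prev")
  bad <- setdiff(names(coef_main), vocab)
  if (length(bad))
    stop("true_params: coef_main names outside the model vocabulary: ",
         paste(bad, collapse = ", "))
  pairs <- .interaction_pairs(spec)
  pair_keys <- paste(pairs$var_a, pairs$var_b, sep = ":")
  bad <- setdiff(names(coef_interaction), pair_keys)
  if (length(bad))
    stop("true_params: coef_interaction names not among the spec's pairs: ",
         paste(bad, collapse = ", "))
  structure(
    list(spec = spec, intercept = intercept, coef_main = coef_main,
         coef_interaction = coef_interaction,
         re_sd_intercept = re_sd_intercept, re_sd_slope = re_sd_slope,
         re_corr = re_corr, gamma_shape = gamma_shape,
         ba_ref = c(mean = ba_ref[[1]], sd = ba_ref[[2]])),
    class = "true_params")
}

#' @export
print.true_params <- function(x, ...) {
  cat(sprintf("<true_params> intercept %.3f, %d nonzero main vars, %d interaction pairs\n",
              x$intercept, length(x$coef_main), length(x$coef_interaction)))
  cat(sprintf("  re sd (int, slope) = (%.3g, %.3g), corr %.2f, gamma shape %.3g\n",
              x$re_sd_intercept, x$re_sd_slope, x$re_corr, x$gamma_shape))
  invisible(x)
}

#' Expand ground-truth parameters to a full design coefficient vector
#'
#' @param truth A [true_params()] object.
#' @return Named numeric vector over [design_columns()] of the truth's spec
#'   (intercept excluded), zeros where the truth names no coefficient.
#' @export
truth_beta <- function(truth) {
  spec <- truth$spec
  cols <- design_columns(spec)
  beta <- setNames(numeric(nrow(cols)), cols$name)
  for (v in names(truth$coef_main)) {
    nms <- if (v == "ba_prev") "ba_prev" else .expand_names(spec, v)
    val <- truth$coef_main[[v]]
    if (length(val) > length(nms))
      stop("truth_beta: too many coefficients for variable ", v)
    beta[nms[seq_along(val)]] <- val
  }
  for (key in names(truth$coef_interaction)) {
    ab <- strsplit(key, ":", fixed = TRUE)[[1]]
    nms <- as.vector(t(outer(.expand_names(spec, ab[1]),
                             .expand_names(spec, ab[2]),
                             paste, sep = ".x.")))
    val <- truth$coef_interaction[[key]]
    if (length(val) > length(nms))
      stop("truth_beta: too many coefficients for interaction ", key)
    beta[nms[seq_along(val)]] <- val
  }
  beta
}

#' Default ground truth of the synthetic growth network
#'
#' A realistic parameterisation used throughout the package's simulation
#' studies: growth around 800 mm^2/yr for an average tree, wetter and warmer
#' low-altitude sites growing faster, summer heat reducing and summer/spring
#' precipitation increasing growth, moderate between-tree heterogeneity and
#' a gamma shape of 8 (coefficient of variation about 35%). All three
#' predictor groups (aridity, geography, seasonal climate) are active. The
#' lagged-basal-area slope is negative (growth of mature trees decelerates
#' with size), which also keeps multi-decade forward simulation stable: a
#' positive total size slope would compound super-exponentially.
#'
#' @param spec A [model_spec()]; defaults to the canonical 21-variable
#'   vocabulary without interaction blocks (the structure used by the
#'   package's parameter-recovery and model-ladder studies).
#' @return A [true_params()] object.
#' @export
default_true_params <- function(spec = model_spec(interactions = character(0))) {
  cm <- list(
    ai = 0.15,
    lat = c(0.10, -0.05),
    alt = c(-0.10, -0.04),
    tmax_SUM = c(-0.12, -0.04),
    tmax_SPR = c(0.06, 0),
    tmin_WIN = c(0.05, 0),
    tmin_pSUM = c(-0.04, 0),
    pp_SUM = 0.12,
    pp_SPR = 0.08,
    pp_pSUM = 0.05,
    ba_prev = -0.08)
  # adapt to reduced vocabularies / basis sizes
  cm <- cm[names(cm) %in% c(spec$variables$name, "ba_prev")]
  cm <- lapply(seq_along(cm), function(i) {
    k <- if (names(cm)[i] == "ba_prev") 1L
         else length(.expand_names(spec, names(cm)[i]))
    cm[[i]][seq_len(min(k, length(cm[[i]])))]
  }) |> setNames(names(cm))
  true_params(
    spec,
    intercept = log(800),
    coef_main = cm,
    re_sd_intercept = 0.25,
    re_sd_slope = 0.08,
    re_corr = 0.2,
    gamma_shape = 8)
}
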