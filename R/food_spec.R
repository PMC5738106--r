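#' Describe a test food entering the digestion protocol
#'
#' A `food_spec` records what a food brings into the protocol: the portion
#' volume fed to the apparatus and the masses the baseline (t = 0) assay
#' reports on a reference 10-ml aliquot of the prepared food. Masses are
#' per-aliquot rather than per-portion because that is what the wet-lab
#' readout measures; the simulator scales them to portion totals internally.
#'
#' @param name Character label for the food.
#' @param portion_volume_ml Portion volume fed into the protocol (ml; the
#'   reference infant meal is 45 ml).
#' @param starch_g Starch mass (g) measured in a 10-ml aliquot of the
#'   prepared food before digestion.
#' @param glucose_g Free D-glucose mass (g) in the same aliquot at t = 0.
#' @param glucogenic_pool_g Starch-equivalent mass (g, same aliquot basis) of
#'   non-starch glucose-yielding saccharides (e.g. fermentation-produced
#'   maltodextrins); digested only in the intestinal phase. Default 0.
#' @param caloric_density_K Caloric density (kcal/ml); may be `NA` (unset).
#' @param initial_pH pH of the prepared food (must lie in (0, 14)).
#' @param needs_pepsin Does the gastric fluid require pepsin? (Protein-rich
#'   foods such as rice cream; isolated rice starch does not.)
#' @param needs_pancrelipase Does the intestinal fluid require pancrelipase?
#'
#' @return An object of class `food_spec` (a named list).
#' @examples
#' food_spec("rice starch 5.5% w/v", 45, starch_g = 0.112, glucose_g = 0.036)
#' @export
food_spec <- function(name, portion_volume_ml, starch_g, glucose_g,
                      glucogenic_pool_g = 0, caloric_density_K = NA_real_,
                      initial_pH = 7, needs_pepsin = FALSE,
                      needs_pancrelipase = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(portion_volume_ml) || portion_volume_ml <= 0)
    stop("portion_volume_ml must be > 0", call. = FALSE)
  for (m in c(starch_g = starch_g, glucose_g = glucose_g,
              glucogenic_pool_g = glucogenic_pool_g)) {
    if (!is.numeric(m) || is.na(m) || m < 0)
      stop("masses must be non-negative numbers", call. = FALSE)
  }
  if (!is.na(initial_pH) && (initial_pH <= 0 || initial_pH >= 14))
    stop("initial_pH must lie strictly between 0 and 14", call. = FALSE)
  structure(
    list(name = name,
         portion_volume_ml = as.numeric(portion_volume_ml),
         starch_g = as.numeric(starch_g),
         glucose_g = as.numeric(glucose_g),
         glucogenic_pool_g = as.numeric(glucogenic_pool_g),
         caloric_density_K = as.numeric(caloric_density_K),
         initial_pH = as.numeric(initial_pH),
         needs_pepsin = isTRUE(needs_pepsin),
         needs_pancrelipase = isTRUE(needs_pancrelipase),
         aliquot_ml = 10),
    class = "food_spec")
}

#' @export
print.food_spec <- function(x, ...) {
  cat(sprintf("<food_spec> %s\n", x$name))
  cat(sprintf("  portion %.1f ml | per-10-ml baseline: starch %.3f g, glucose %.3f g",
              x$portion_volume_ml, x$starch_g, x$glucose_g))
  if (x$glucogenic_pool_g > 0)
    cat(sprintf(", glucogenic pool %.3f g", x$glucogenic_pool_g))
  cat(sprintf("\n  pH %.1f | pepsin: %s | pancrelipase: %s\n",
              x$initial_pH,
              if (x$needs_pepsin) "yes" else "no",
              if (x$needs_pancrelipase) "yes" else "no"))
  invisible(x)
}
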