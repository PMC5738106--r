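# Fluid-volume planning, simulated-fluid recipes and enzyme dosing for the
# M.I.D.A. protocol. Every compartment dilutes the incoming stream 50:50
# (v/v) with its simulated fluid (SSF, SGF, SIF), so each fluid volume equals
# the volume of the stream it meets after any sampling losses.

#' Plan simulated-fluid volumes under the 50:50 mixing rule
#'
#' At every stage the simulated fluid volume equals the volume of the stream
#' arriving from the previous compartment, after sampling withdrawals:
#' SSF matches the food portion, SGF matches the bolus actually entering the
#' stomach (oral sample removed), SIF matches the chyme actually delivered
#' through the pylorus (gastric samples removed).
#'
#' @param food_volume_ml Food portion volume (ml), > 0 (or 0 for the empty
#'   protocol).
#' @param oral_sample_ml Bolus volume withdrawn for analysis after the oral
#'   phase (ml, >= 0).
#' @param n_gastric_samples Number of gastric samples withdrawn.
#' @param gastric_sample_ml Volume of each gastric sample (ml, >= 0).
#'
#' @return A `volume_plan` (named list): `food_volume_ml`, `ssf_ml`,
#'   `gastric_food_input_ml`, `sgf_ml`, `gastric_total_ml`,
#'   `gastric_sampled_ml`, `chyme_delivered_ml`, `sif_ml`, `chyle_final_ml`.
#' @examples
#' # reference infant protocol: 45 ml portion, one 10-ml oral sample,
#' # eight 10-ml gastric samples -> SSF 45, SGF 80, SIF 80, chyle 160 ml
#' plan_fluid_volumes(45, 10, 8, 10)
#' @export
plan_fluid_volumes <- function(food_volume_ml, oral_sample_ml = 0,
                               n_gastric_samples = 0, gastric_sample_ml = 0) {
  if (food_volume_ml < 0) stop("food_volume_ml must be >= 0", call. = FALSE)
  if (oral_sample_ml < 0 || gastric_sample_ml < 0 || n_gastric_samples < 0)
    stop("sample volumes and counts must be >= 0", call. = FALSE)

  ssf <- food_volume_ml
  oral_total <- food_volume_ml + ssf
  if (oral_sample_ml > oral_total)
    stop("infeasible sampling plan: oral sample exceeds oral contents",
         call. = FALSE)
  gastric_in <- oral_total - oral_sample_ml
  sgf <- gastric_in
  gastric_total <- gastric_in + sgf
  gastric_sampled <- n_gastric_samples * gastric_sample_ml
  if (gastric_sampled > gastric_total)
    stop("infeasible sampling plan: gastric samples exceed gastric contents",
         call. = FALSE)
  chyme <- gastric_total - gastric_sampled
  sif <- chyme
  structure(
    list(food_volume_ml = food_volume_ml, ssf_ml = ssf,
         gastric_food_input_ml = gastric_in, sgf_ml = sgf,
         gastric_total_ml = gastric_total,
         gastric_sampled_ml = gastric_sampled,
         chyme_delivered_ml = chyme, sif_ml = sif,
         chyle_final_ml = chyme + sif),
    class = "volume_plan")
}

#' @export
print.volume_plan <- function(x, ...) {
  cat("<volume_plan> (50:50 v/v mixing at each compartment)\n")
  cat(sprintf("  food %g ml + SSF %g ml -> oral %g ml (sampled %g ml)\n",
              x$food_volume_ml, x$ssf_ml, x$food_volume_ml + x$ssf_ml,
              x$food_volume_ml + x$ssf_ml - x$gastric_food_input_ml))
  cat(sprintf("  bolus %g ml + SGF %g ml -> gastric %g ml (sampled %g ml)\n",
              x$gastric_food_input_ml, x$sgf_ml, x$gastric_total_ml,
              x$gastric_sampled_ml))
  cat(sprintf("  chyme %g ml + SIF %g ml -> chyle %g ml\n",
              x$chyme_delivered_ml, x$sif_ml, x$chyle_final_ml))
  invisible(x)
}

#' Default sampling plan of the infant digestion protocol
#'
#' Twenty-one samples per run: one pre-digestion baseline of the prepared
#' food, one oral bolus at 2 min, eight gastric samples every 15 min
#' (17-122 min), eight intestinal samples every 15 min (137-242 min) and
#' three terminal drain samples every 2 min (244-248 min).
#'
#' @param sample_volume_ml Volume of each withdrawn sample (ml, default 10).
#' @return A data frame with columns `time_min`, `compartment`,
#'   `sample_volume_ml`, `purpose`.
#' @export
default_sampling_plan <- function(sample_volume_ml = 10) {
  stopifnot(sample_volume_ml > 0)
  times <- c(0, 2, seq(17, 122, by = 15), seq(137, 242, by = 15),
             c(244, 246, 248))
  data.frame(
    time_min = times,
    compartment = c("food", "oral", rep("gastric", 8), rep("intestinal", 11)),
    sample_volume_ml = sample_volume_ml,
    purpose = c("baseline", "oral", rep("gastric", 8),
                rep("intestinal", 8), rep("drain", 3)),
    stringsAsFactors = FALSE)
}

.fluid_compartment <- c(SSF = "oral", SGF = "gastric", SIF = "intestinal")
.fluid_target_pH <- c(SSF = 7, SGF = 3, SIF = 7)
# fluid volumes prepared for the reference 45-ml protocol (water to volume)
.fluid_final_volume_ml <- c(SSF = 45, SGF = 80, SIF = 80)

.normalize_food_class <- function(food_class) {
  fc <- switch(food_class,
               rice_starch = , rice_starch_classical = ,
               rice_starch_htst = "rice_starch",
               rice_cream_basic = "rice_cream_basic",
               rice_cream_premium = "rice_cream_premium",
               stop(sprintf("unknown food class '%s'", food_class),
                    call. = FALSE))
  fc
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "midasim")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  path
}

#' Electrolyte stock composition of the simulated digestive fluids
#'
#' Volumes (ml) of each electrolyte stock solution making up 400 ml of
#' concentrated SSF, SGF and SIF electrolyte mix.
#'
#' @return A data frame with columns `stock`, `ssf_ml`, `sgf_ml`, `sif_ml`.
#' @export
electrolyte_stocks <- function() {
  utils::read.csv(.extdata("electrolyte_stocks.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Build the recipe of a simulated digestive fluid
#'
#' Returns the tabulated recipe for SSF, SGF or SIF for a food class:
#' electrolyte stock volume, enzyme amounts with their target activities in
#' the final compartment contents, CaCl2 and the pre-determined pH-adjustment
#' acid/base volumes, with distilled water up to the final fluid volume.
#' Recipes are stored as a versioned data fixture so other consensus-protocol
#' variants can be swapped in. The SGF recipe carries pepsin only for the
#' protein-containing rice-cream foods.
#'
#' @param fluid_name One of `"SSF"`, `"SGF"`, `"SIF"`.
#' @param food_class One of `"rice_starch"` (aliases `"rice_starch_classical"`,
#'   `"rice_starch_htst"`), `"rice_cream_basic"`, `"rice_cream_premium"`.
#' @return A `fluid_recipe` (named list) with the component table in
#'   `$components`.
#' @examples
#' make_fluid_recipe("SGF", "rice_cream_basic")
#' @export
make_fluid_recipe <- function(fluid_name, food_class) {
  if (!fluid_name %in% names(.fluid_compartment))
    stop(sprintf("unknown fluid '%s' (expected SSF, SGF or SIF)", fluid_name),
         call. = FALSE)
  fc <- .normalize_food_class(food_class)
  all <- utils::read.csv(.extdata("fluid_recipes.csv"),
                         stringsAsFactors = FALSE)
  comp <- all[all$food_class == fc & all$fluid == fluid_name,
              c("component", "amount", "unit", "activity", "activity_unit")]
  rownames(comp) <- NULL
  final_ml <- unname(.fluid_final_volume_ml[fluid_name])
  vol_components <- comp$amount[comp$unit == "ml"]
  stopifnot(sum(vol_components) <= final_ml)
  is_enz <- !(comp$component %in%
                c("electrolyte_stock", "CaCl2 0.3 M", "HCl 1 M", "NaHCO3 1 M"))
  structure(
    list(fluid_name = fluid_name,
         compartment = unname(.fluid_compartment[fluid_name]),
         food_class = fc,
         components = comp,
         enzymes = comp[is_enz, , drop = FALSE],
         electrolyte_stock_ml = sum(comp$amount[comp$component ==
                                                  "electrolyte_stock"]),
         cacl2_ml = sum(comp$amount[comp$component == "CaCl2 0.3 M"]),
         hcl_1M_ml = sum(comp$amount[comp$component == "HCl 1 M"]),
         nahco3_1M_ml = sum(comp$amount[comp$component == "NaHCO3 1 M"]),
         water_to_volume_ml = final_ml,
         target_pH = unname(.fluid_target_pH[fluid_name])),
    class = "fluid_recipe")
}

#' @export
print.fluid_recipe <- function(x, ...) {
  cat(sprintf("<fluid_recipe> %s (%s compartment) for %s, pH %g, to %g ml\n",
              x$fluid_name, x$compartment, x$food_class, x$target_pH,
              x$water_to_volume_ml))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Pancrelipase dosing by body weight
#'
#' Pancreatic enzymes are dosed as pancrelipase by lipase units per kg of
#' body weight per meal; the amylase and protease doses follow from the
#' capsule composition ratios.
#'
#' Note: for the reference 7.695-kg infant the capsule ratio yields a
#' protease dose of 461.7 U, while the published protocol prints 770 U; the
#' printed figure is preserved as [creon_printed_protease_U] and never
#' silently substituted.
#'
#' @param weight_kg Body weight (kg), > 0.
#' @param lipase_units_per_kg Lipase dose rule (U/kg/meal, default 1000).
#' @param capsule_lipase,capsule_amylase,capsule_protease Enzyme content of
#'   one capsule (Ph.Eur. units; defaults are the Creon 10000 composition).
#' @return Named numeric vector with `lipase_U`, `amylase_U`, `protease_U`.
#' @examples
#' dose_pancrelipase(7.695) # lipase 7695 U, amylase 6156 U
#' @export
dose_pancrelipase <- function(weight_kg, lipase_units_per_kg = 1000,
                              capsule_lipase = 10000, capsule_amylase = 8000,
                              capsule_protease = 600) {
  if (weight_kg <= 0) stop("weight_kg must be > 0", call. = FALSE)
  stopifnot(lipase_units_per_kg > 0, capsule_lipase > 0,
            capsule_amylase > 0, capsule_protease > 0)
  lip <- weight_kg * lipase_units_per_kg
  c(lipase_U = lip,
    amylase_U = lip * capsule_amylase / capsule_lipase,
    protease_U = lip * capsule_protease / capsule_lipase)
}

#' Protease dose printed in the published protocol
#'
#' The published protocol states 770 protease units for the 7.695-kg
#' reference infant, which is inconsistent with its own capsule composition
#' (600 protease U per 10000 lipase U gives 461.7 U). Both numbers are kept;
#' [dose_pancrelipase()] follows the capsule ratio.
#' @export
creon_printed_protease_U <- 770

#' Duodenal glucoamylase activity from pancreatic alpha-amylase activity
#'
#' Duodenal aspirates show a glucoamylase to pancreatic alpha-amylase
#' activity ratio of 0.11, which fixes the glucoamylase dose once the
#' amylase activity of the intestinal fluid is chosen.
#'
#' @param pancreatic_amylase_activity_U_per_ml Activity (U/ml), >= 0.
#' @return Glucoamylase activity (U/ml of final intestinal contents).
#' @examples
#' glucoamylase_activity(170.5) # 18.755 U/ml
#' @export
glucoamylase_activity <- function(pancreatic_amylase_activity_U_per_ml) {
  if (pancreatic_amylase_activity_U_per_ml < 0)
    stop("activity must be >= 0", call. = FALSE)
  0.11 * pancreatic_amylase_activity_U_per_ml
}
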