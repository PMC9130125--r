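## Molar masses (g/mol) of the major-element oxides used by the weathering
## indices.
OXIDE_MOLAR_MASS <- c(Al2O3 = 101.96, CaO = 56.08, Na2O = 61.98,
                      K2O = 94.20, MgO = 40.30, MnO = 70.94)

#' Convert oxide weight percent to molar proportions
#'
#' @param wt Named numeric vector of oxide weight percents. Names must be a
#'   subset of `Al2O3, CaO, Na2O, K2O, MgO, MnO`.
#' @return Named numeric vector of moles (per 100 g of sample).
#' @export
to_molar <- function(wt) {
  wt <- unlist(wt)
  unknown <- setdiff(names(wt), names(OXIDE_MOLAR_MASS))
  if (length(unknown))
    stop("unknown oxide key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(wt) | wt < 0))
    stop("oxide weight percents must be finite and >= 0", call. = FALSE)
  wt / OXIDE_MOLAR_MASS[names(wt)]
}

## Silicate-bound Ca. The profiles this chain targets are carbonate-free, so
## by default CaO* = CaO; `method = "mclennan"` applies the common cap
## CaO* = min(CaO, Na2O) for carbonate/apatite-suspect samples.
cao_star <- function(molar, method = c("as_is", "mclennan")) {
  method <- match.arg(method)
  ca <- molar[["CaO"]]
  if (method == "mclennan") min(ca, molar[["Na2O"]])
  else ca
}

#' Chemical index of alteration (CIA)
#'
#' `CIA = 100 * Al2O3 / (Al2O3 + CaO* + Na2O + K2O)` in molar proportions,
#' where CaO* is silicate-bound Ca.
#'
#' @param molar Named molar proportions (see [to_molar()]); requires Al2O3,
#'   CaO, Na2O and K2O.
#' @param cao_method `"as_is"` (default; carbonate-free samples) or
#'   `"mclennan"` (cap CaO* at Na2O).
#' @return CIA in `[0, 100]`.
#' @export
cia <- function(molar, cao_method = "as_is") {
  al <- molar[["Al2O3"]]
  if (!is.finite(al) || al <= 0) stop("Al2O3 must be > 0", call. = FALSE)
  den <- al + cao_star(molar, cao_method) + molar[["Na2O"]] + molar[["K2O"]]
  if (den <= 0) stop("zero denominator in CIA", call. = FALSE)
  100 * al / den
}

#' Potassium-free chemical index of alteration (CIA-K)
#'
#' `CIA-K = 100 * Al2O3 / (Al2O3 + CaO* + Na2O)` in molar proportions;
#' dropping K avoids bias from potash metasomatism.
#'
#' @inheritParams cia
#' @return CIA-K in `[0, 100]`.
#' @export
cia_k <- function(molar, cao_method = "as_is") {
  al <- molar[["Al2O3"]]
  if (!is.finite(al) || al <= 0) stop("Al2O3 must be > 0", call. = FALSE)
  den <- al + cao_star(molar, cao_method) + molar[["Na2O"]]
  if (den <= 0) stop("zero denominator in CIA-K", call. = FALSE)
  100 * al / den
}

#' Authigenic-potassium correction of the CIA
#'
#' Restores pre-metasomatism K before computing the CIA: with
#' `m = K / (Al + CaO* + Na + K)` taken from the parent material, the
#' corrected potassium is `K_corr = m * (Al + CaO* + Na) / (1 - m)` and the
#' CIA is recomputed with it. A horizon whose K is already at the parent
#' proportion is a fixed point, so the correction is idempotent.
#'
#' @param molar Named molar proportions of the horizon.
#' @param parent_molar Named molar proportions of the parent material.
#' @inheritParams cia
#' @return List with `cia_corrected`, `k_corrected` (molar) and `m` (parent K
#'   proportion).
#' @export
k_correction <- function(molar, parent_molar, cao_method = "as_is") {
  base_p <- parent_molar[["Al2O3"]] + cao_star(parent_molar, cao_method) +
    parent_molar[["Na2O"]]
  m <- parent_molar[["K2O"]] / (base_p + parent_molar[["K2O"]])
  if (!is.finite(m) || m >= 1)
    stop("parent K proportion m must be < 1", call. = FALSE)
  base_h <- molar[["Al2O3"]] + cao_star(molar, cao_method) + molar[["Na2O"]]
  k_corr <- m * base_h / (1 - m)
  corrected <- molar
  corrected[["K2O"]] <- k_corr
  list(cia_corrected = cia(corrected, cao_method), k_corrected = k_corr, m = m)
}

#' Mean annual precipitation from CIA-K
#'
#' `MAP = C1 * exp(C2 * CIA-K)` with the standard published calibration
#' `C1 = 221.1 mm`, `C2 = 0.0197` as shipped defaults.
#'
#' @param ciak CIA-K value(s) in `[0, 100]`.
#' @param c1,c2 Calibration coefficients (config-overridable).
#' @return Mean annual precipitation in mm/yr.
#' @export
map_from_ciak <- function(ciak, c1 = 221.1, c2 = 0.0197) {
  if (any(!is.finite(ciak) | ciak < 0 | ciak > 100))
    stop("CIA-K must lie in [0, 100]", call. = FALSE)
  c1 * exp(c2 * ciak)
}

#' Land surface temperature from the corrected CIA
#'
#' Linear transfer `T = a * CIA + b`. The shipped default pair
#' (`a = 0.56`, `b = -25.7`) is provisional: calibrations of this transfer
#' vary between soil-forming settings, so production use should supply
#' coefficients explicitly (`strict = TRUE` refuses the defaults).
#'
#' @param cia_corrected CIA (authigenic-K corrected) in `[0, 100]`.
#' @param a,b Transfer coefficients (degC per CIA unit; intercept degC).
#' @param strict If `TRUE`, error unless both coefficients were supplied.
#' @return Land surface temperature in degrees Celsius.
#' @export
lst_from_cia <- function(cia_corrected, a = 0.56, b = -25.7, strict = FALSE) {
  if (strict && (missing(a) || missing(b)))
    stop("strict mode: supply CIA->LST coefficients explicitly", call. = FALSE)
  if (any(!is.finite(cia_corrected) | cia_corrected < 0 | cia_corrected > 100))
    stop("CIA must lie in [0, 100]", call. = FALSE)
  a * cia_corrected + b
}

#' Default energy-balance transfer configuration
#'
#' Shipped stand-in transfer functions for precipitation energy (Eppt) and
#' evapotranspiration (ET); both are synthetic placeholders with the right
#' qualitative behaviour and units, intended to be replaced by calibrated
#' coefficients via config.
#'
#' * `Eppt = MAP[kg m-2 yr-1] * cp[MJ kg-1 K-1] * (LST - t_ref)` — sensible
#'   heat delivered by rain relative to a reference temperature.
#' * `ET = pet_coeff * max(LST, 0) [mm] * latent_heat [MJ kg-1]` — a
#'   temperature-based annual potential-evapotranspiration approximation
#'   converted to latent energy.
#'
#' @return List of coefficients consumed by [eppt_et()].
#' @export
default_energy_transfer <- function() {
  list(cp = 4.186e-3,      # MJ kg-1 K-1, specific heat of water
       t_ref = 0,          # degC reference temperature for Eppt
       pet_coeff = 58.93,  # mm yr-1 per degC, annual PET per degree
       latent_heat = 2.45) # MJ kg-1, latent heat of vaporization
}

#' Precipitation energy and evapotranspiration from MAP and LST
#'
#' @param map_mm_yr Mean annual precipitation, mm/yr (> 0).
#' @param lst_celsius Land surface temperature, degC.
#' @param transfer Coefficient list, see [default_energy_transfer()].
#' @param strict If `TRUE`, error unless `transfer` was supplied explicitly.
#' @return List with `eppt` and `et`, both MJ m-2 yr-1.
#' @export
eppt_et <- function(map_mm_yr, lst_celsius,
                    transfer = default_energy_transfer(), strict = FALSE) {
  if (strict && missing(transfer))
    stop("strict mode: supply Eppt/ET transfer coefficients explicitly",
         call. = FALSE)
  if (any(!is.finite(map_mm_yr) | map_mm_yr <= 0))
    stop("MAP must be > 0", call. = FALSE)
  eppt <- map_mm_yr * transfer$cp * (lst_celsius - transfer$t_ref)
  et <- transfer$pet_coeff * pmax(lst_celsius, 0) * transfer$latent_heat
  list(eppt = eppt, et = et)
}

#' Default humidity-province boundaries
#'
#' Ordered non-crossing polylines in (ET, Eppt) space separating humidity
#' provinces from driest to wettest, with an associated floral regime per
#' province. These boundaries are synthetic placeholders consistent with the
#' [default_energy_transfer()] units, shipped so the classification is total
#' and testable; replace via config for calibrated work.
#'
#' @return List with `lines` (each a data.frame `et`, `eppt`, ordered driest
#'   to wettest), `provinces` (length `length(lines) + 1` labels) and
#'   `floral_regimes` (same length as `provinces`).
#' @export
default_humidity_boundaries <- function() {
  slope_line <- function(s) data.frame(et = c(0, 6000), eppt = c(0, 6000 * s))
  list(lines = lapply(c(0.005, 0.015, 0.03, 0.06), slope_line),
       provinces = c("arid", "semiarid", "subhumid", "humid", "perhumid"),
       floral_regimes = c("desert scrub", "xeric woodland", "seasonal forest",
                          "temperate forest", "rainforest"))
}

interp_polyline <- function(line, et) {
  # linear interpolation with end-segment extrapolation
  x <- line$et; y <- line$eppt; n <- length(x)
  vapply(et, function(e) {
    if (e <= x[1]) y[1] + (e - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
    else if (e >= x[n]) y[n] + (e - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    else stats::approx(x, y, xout = e)$y
  }, numeric(1))
}

validate_boundaries <- function(boundaries) {
  lines <- boundaries$lines
  if (length(boundaries$provinces) != length(lines) + 1L)
    stop("need one province label more than boundary lines", call. = FALSE)
  xs <- sort(unique(c(unlist(lapply(lines, `[[`, "et")),
                      seq(0, 6000, length.out = 25))))
  vals <- vapply(lines, interp_polyline, numeric(length(xs)), et = xs)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(xs))
  # reject proper crossings; touching (e.g. a shared origin) is tolerated,
  # with on-boundary points resolved by the wetter-region tie rule
  if (ncol(vals) > 1 && any(apply(vals, 1, diff) < -1e-9))
    stop("humidity-province boundary polylines cross", call. = FALSE)
  invisible(TRUE)
}

#' Humidity province and floral regime of an (ET, Eppt) point
#'
#' The configured boundary polylines partition the (ET, Eppt) plane into
#' ordered regions from driest (below the lowest line) to wettest (above the
#' highest). Points lying exactly on a boundary are assigned to the wetter
#' region.
#'
#' @param eppt Precipitation energy, MJ m-2 yr-1.
#' @param et Evapotranspiration, MJ m-2 yr-1.
#' @param boundaries See [default_humidity_boundaries()].
#' @return List with `province` and `floral_regime` labels (vectorized).
#' @export
humidity_province <- function(eppt, et,
                              boundaries = default_humidity_boundaries()) {
  validate_boundaries(boundaries)
  n <- max(length(eppt), length(et))
  eppt <- rep_len(eppt, n); et <- rep_len(et, n)
  counts <- integer(n)
  for (line in boundaries$lines)
    counts <- counts + (eppt >= interp_polyline(line, et))  # tie -> wetter
  list(province = boundaries$provinces[counts + 1L],
       floral_regime = boundaries$floral_regimes[counts + 1L])
}

#' Construct a paleosol profile
#'
#' @param horizons Data frame with columns `horizon`, `depth_cm` and the
#'   oxide weight percents `Al2O3, CaO, Na2O, K2O, MgO, MnO`, ordered surface
#'   to parent.
#' @param parent_index Row index of the parent material (default: deepest).
#' @return Object of class `paleosol_profile`.
#' @export
paleosol_profile <- function(horizons, parent_index = nrow(horizons)) {
  req <- c("horizon", "depth_cm", names(OXIDE_MOLAR_MASS))
  missing_cols <- setdiff(req, names(horizons))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  ox <- as.matrix(horizons[, names(OXIDE_MOLAR_MASS)])
  if (any(!is.finite(ox) | ox < 0))
    stop("oxide weight percents must be finite and >= 0", call. = FALSE)
  if (is.unsorted(horizons$depth_cm, strictly = FALSE))
    stop("horizon depths must increase from surface to parent", call. = FALSE)
  if (parent_index < 1 || parent_index > nrow(horizons))
    stop("parent_index out of range", call. = FALSE)
  structure(list(horizons = as.data.frame(horizons),
                 parent_index = as.integer(parent_index)),
            class = "paleosol_profile")
}

#' @export
print.paleosol_profile <- function(x, ...) {
  cat(sprintf("<paleosol_profile: %d horizons (parent: '%s' at %.0f cm)>\n",
              nrow(x$horizons), x$horizons$horizon[x$parent_index],
              x$horizons$depth_cm[x$parent_index]))
  invisible(x)
}

profile_molar <- function(profile) {
  lapply(seq_len(nrow(profile$horizons)), function(i)
    to_molar(unlist(profile$horizons[i, names(OXIDE_MOLAR_MASS)])))
}

#' Profile quality control: CIA-K contrast between B horizons and parent
#'
#' A profile records pedogenesis (rather than unaltered parent chemistry)
#' when the mean CIA-K of its B horizons differs from the parent CIA-K by
#' more than 5%.
#'
#' @param profile A [paleosol_profile()]. B horizons are those whose label
#'   starts with "B".
#' @inheritParams cia
#' @return List with `ciak_contrast_percent`, `passes`, `ciak_b_mean`,
#'   `ciak_parent`.
#' @export
profile_qc <- function(profile, cao_method = "as_is") {
  molar <- profile_molar(profile)
  ciak <- vapply(molar, cia_k, numeric(1), cao_method = cao_method)
  is_b <- grepl("^B", profile$horizons$horizon) &
    seq_along(ciak) != profile$parent_index
  if (!any(is_b)) stop("no B horizon in profile", call. = FALSE)
  ck_parent <- ciak[profile$parent_index]
  if (ck_parent == 0) stop("parent CIA-K is zero", call. = FALSE)
  contrast <- 100 * abs(mean(ciak[is_b]) - ck_parent) / ck_parent
  list(ciak_contrast_percent = contrast, passes = contrast > 5,
       ciak_b_mean = mean(ciak[is_b]), ciak_parent = ck_parent)
}

#' Full paleosol climate-proxy chain
#'
#' Per horizon: molar conversion, CIA, authigenic-K-corrected CIA, CIA-K,
#' MAP from CIA-K, LST from corrected CIA, Eppt/ET, and the humidity-province
#' classification.
#'
#' @param profile A [paleosol_profile()].
#' @param lst_coef List `a`, `b` for [lst_from_cia()].
#' @param map_coef List `c1`, `c2` for [map_from_ciak()].
#' @param transfer Energy transfer coefficients, see [eppt_et()].
#' @param boundaries Humidity-province boundaries, see [humidity_province()].
#' @inheritParams cia
#' @return Data frame of class `climate_estimate`, one row per horizon.
#' @export
paleosol_climate <- function(profile,
                             lst_coef = list(a = 0.56, b = -25.7),
                             map_coef = list(c1 = 221.1, c2 = 0.0197),
                             transfer = default_energy_transfer(),
                             boundaries = default_humidity_boundaries(),
                             cao_method = "as_is") {
  molar <- profile_molar(profile)
  parent <- molar[[profile$parent_index]]
  rows <- lapply(seq_along(molar), function(i) {
    m <- molar[[i]]
    kc <- k_correction(m, parent, cao_method)
    ck <- cia_k(m, cao_method)
    map <- map_from_ciak(ck, map_coef$c1, map_coef$c2)
    lst <- lst_from_cia(kc$cia_corrected, lst_coef$a, lst_coef$b)
    en <- eppt_et(map, lst, transfer)
    hp <- humidity_province(en$eppt, en$et, boundaries)
    data.frame(horizon = profile$horizons$horizon[i],
               depth_cm = profile$horizons$depth_cm[i],
               cia = cia(m, cao_method),
               cia_corrected = kc$cia_corrected,
               cia_k = ck, map_mm_yr = map, lst_celsius = lst,
               eppt = en$eppt, et = en$et,
               humidity_province = hp$province,
               floral_regime = hp$floral_regime,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("climate_estimate", class(out))
  out
}

#' Write / read a paleosol profile as CSV
#'
#' Plain CSV with columns `horizon, depth_cm, Al2O3, CaO, Na2O, K2O, MgO,
#' MnO` (wt%), ordered surface to parent; the parent row is marked by its
#' label.
#'
#' @param profile A [paleosol_profile()].
#' @param path File path.
#' @return `read_paleosol_csv` returns a [paleosol_profile()];
#'   `write_paleosol_csv` returns `path` invisibly.
#' @export
write_paleosol_csv <- function(profile, path) {
  write.csv(profile$horizons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_paleosol_csv
#' @param parent_index Parent row; default the deepest horizon.
#' @export
read_paleosol_csv <- function(path, parent_index = NULL) {
  h <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(parent_index)) parent_index <- nrow(h)
  paleosol_profile(h, parent_index)
}
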