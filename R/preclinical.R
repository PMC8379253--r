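#' Caliper tumor volume
#'
#' V = 0.5 x a x b^2, with a and b the long and short tumor diameters in mm.
#'
#' @param a long diameter, mm (a >= b).
#' @param b short diameter, mm (b >= 0).
#' @return volume in mm^3 (vectorized).
#' @export
tumorVolume <- function(a, b) {
    if (any(b < 0)) stop("diameters must be nonnegative")
    if (any(b > a)) stop("long diameter a must be >= short diameter b")
    0.5 * a * b^2
}

# Resolve volumes from a growth table: use the volume column when present,
# otherwise compute from the caliper diameters.
curveVolumes <- function(curves) {
    need <- c("animal", "arm", "day")
    if (!all(need %in% colnames(curves)))
        stop("growth table needs columns: ", paste(need, collapse = ", "))
    if (!"volume" %in% colnames(curves) || any(is.na(curves$volume))) {
        if (!all(c("a_mm", "b_mm") %in% colnames(curves)))
            stop("need either a volume column or a_mm/b_mm diameters")
        curves$volume <- tumorVolume(curves$a_mm, curves$b_mm)
    }
    curves
}

#' Tumor growth inhibition at a readout day
#'
#' TGI% = [1 - (TVi - TV0) / (TVvi - TVv0)] x 100, where TVi and TV0 are the
#' treated arm's mean volumes at the readout day and day 0, and TVvi, TVv0
#' the vehicle arm's. Day 0 is the first measurement day common to both arms.
#' Animals missing either time point are excluded from both means
#' (complete-case), and the exclusion is reported.
#'
#' @param curves growth-curve data.frame (animal, arm in
#'   \{vehicle, treated\}, day, volume or a_mm/b_mm).
#' @param day readout day.
#' @return list(day, day0, TV0, TVi, TVv0, TVvi, tgi_percent, n_treated,
#'   n_vehicle, excluded_animals).
#' @export
tgi <- function(curves, day) {
    curves <- curveVolumes(curves)
    if (!all(c("vehicle", "treated") %in% curves$arm))
        stop("both a 'vehicle' and a 'treated' arm are required")
    day0 <- max(vapply(c("vehicle", "treated"), function(a)
        min(curves$day[curves$arm == a]), numeric(1)))
    if (!any(curves$day == day)) stop("no measurements at day ", day)
    armMeans <- function(a) {
        sub <- curves[curves$arm == a, , drop = FALSE]
        v0 <- sub[sub$day == day0, c("animal", "volume")]
        vi <- sub[sub$day == day, c("animal", "volume")]
        common <- intersect(v0$animal, vi$animal)
        excl <- setdiff(unique(sub$animal), common)
        if (!length(common))
            stop("arm '", a, "' has no animal measured at both day ", day0,
                 " and day ", day)
        list(m0 = mean(v0$volume[match(common, v0$animal)]),
             mi = mean(vi$volume[match(common, vi$animal)]),
             n = length(common), excluded = excl)
    }
    tr <- armMeans("treated"); ve <- armMeans("vehicle")
    if (ve$mi == ve$m0)
        stop("TGI undefined: vehicle arm mean volume unchanged (TVvi == TVv0)")
    list(day = day, day0 = day0,
         TV0 = tr$m0, TVi = tr$mi, TVv0 = ve$m0, TVvi = ve$mi,
         tgi_percent = (1 - (tr$mi - tr$m0) / (ve$mi - ve$m0)) * 100,
         n_treated = tr$n, n_vehicle = ve$n,
         excluded_animals = c(tr$excluded, ve$excluded))
}
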