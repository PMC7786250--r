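# First-order histogram features of the voxel-wise NWU maps. The N = 8
# grade counts Y1..Y8 plus five summary parameters of the count vector
# (population SD, min-to-max slope, Shannon entropy, skewness, excess
# kurtosis) give 13 imaging features per subject.

#' Discrete NWU-grade histogram of ratio maps
#'
#' Bins every retained map voxel into `n_grades` equal-width grades over
#' `[0, 1]`; bins are half-open `[edge_i, edge_{i+1})` with the last bin
#' closed at 1, so each voxel is counted exactly once (3600 voxels for four
#' full 30 x 30 maps).
#'
#' @param maps a `ratio_map_set` from [compute_ratio_maps()], or a list of
#'   numeric matrices with values in `[0, 1]` (NA = excluded).
#' @param n_grades number of grades N (default 8).
#' @return An `nwu_histogram`: `counts` (Y_n), `proportions` (p_n),
#'   `grades` (bin midpoints r_n), `bin_edges`, `n_grades`, `total`.
#' @export
build_histogram <- function(maps, n_grades = 8) {
  if (n_grades < 2) stop("n_grades must be >= 2")
  if (inherits(maps, "ratio_map_set")) maps <- maps$maps
  if (is.matrix(maps) || is.numeric(maps)) maps <- list(maps)
  v <- unlist(lapply(maps, as.numeric))
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no retained voxels to bin")
  if (any(v < 0 | v > 1)) stop("map values must lie in [0, 1]")
  n_grades <- as.integer(n_grades)
  idx <- pmin(floor(v * n_grades) + 1L, n_grades)   # last bin closed at 1
  counts <- tabulate(idx, nbins = n_grades)
  edges <- seq(0, 1, length.out = n_grades + 1)
  structure(list(counts = counts, proportions = counts / length(v),
                 grades = (edges[-1] + edges[-(n_grades + 1)]) / 2,
                 bin_edges = edges, n_grades = n_grades, total = length(v)),
            class = "nwu_histogram")
}

#' Shannon entropy of histogram proportions
#'
#' `H = -sum(p_n log(p_n))` with `0 log 0 := 0`; base 2 by default, so H is
#' in bits and bounded by `log2(N)`. H summarizes the average information
#' content of the NWU map.
#'
#' @param p non-negative proportions summing to 1.
#' @param base logarithm base (2 for bits, `exp(1)` for nats).
#' @return Scalar entropy.
#' @export
histogram_entropy <- function(p, base = 2) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Population skewness of a count vector
#'
#' `g = sum((Y_i - Ybar)^3) / (N s^3)` with `s` the population (1/N)
#' standard deviation; exactly 0 for data symmetric about its mean. A
#' zero-variance vector returns 0 with attribute `degenerate = TRUE`.
#'
#' @param y numeric vector, length >= 2.
#' @return Scalar skewness.
#' @export
vector_skewness <- function(y) {
  stopifnot(length(y) >= 2)
  m <- mean(y); s <- sqrt(mean((y - m)^2))
  if (s == 0) return(structure(0, degenerate = TRUE))
  mean((y - m)^3) / s^3
}

#' Population excess kurtosis of a count vector
#'
#' `k = sum((Y_i - Ybar)^4) / (N s^4) - 3`: 0 for a normal distribution,
#' positive for heavy tails, negative for light tails, and never below -2.
#' A zero-variance vector returns 0 with attribute `degenerate = TRUE`.
#'
#' @param y numeric vector, length >= 2.
#' @return Scalar excess kurtosis.
#' @export
vector_kurtosis <- function(y) {
  stopifnot(length(y) >= 2)
  m <- mean(y); s <- sqrt(mean((y - m)^2))
  if (s == 0) return(structure(0, degenerate = TRUE))
  mean((y - m)^4) / s^4 - 3
}

#' Min-to-max slope of the grade counts
#'
#' The gradient between the minimum and maximum points of `Y_1..Y_N`:
#' `(Y_max - Y_min) / (index_max - index_min)` with 1-based grade indices,
#' taking the first occurrence on ties; 0 for a constant vector.
#'
#' @param y numeric vector of grade counts, length >= 2.
#' @return Scalar slope (counts per grade).
#' @export
histogram_slope <- function(y) {
  stopifnot(length(y) >= 2)
  imin <- which.min(y); imax <- which.max(y)
  if (imin == imax) return(0)
  (y[imax] - y[imin]) / (imax - imin)
}

#' Assemble a subject's feature vector
#'
#' Combines the scalar NWU, the 13 imaging features (Y1..Y8, std, slope,
#' entropy, skewness, kurtosis) and/or the three clinical covariates (age,
#' gender, NIHSS) into one named numeric vector, in the fixed order
#' `nwu, age, gender, nihss, y1..y8, std, slope, entropy, skewness,
#' kurtosis` restricted to the requested set. Gender is encoded
#' female = 1, male = 0.
#'
#' @param hist an `nwu_histogram` (needed for the imaging sets).
#' @param ip_nwu scalar NWU of the subject.
#' @param clinical list or one-row data.frame with `age`, `gender`
#'   (`"female"`/`"male"` or 0/1) and `nihss`; required for clinical sets.
#' @param set `"nwu_imaging"` (14 values), `"nwu_clinical"` (4) or
#'   `"nwu_clinical_imaging"` (17).
#' @return Named numeric vector.
#' @export
assemble_features <- function(hist = NULL, ip_nwu, clinical = NULL,
                              set = c("nwu_clinical_imaging", "nwu_imaging",
                                      "nwu_clinical")) {
  set <- match.arg(set)
  out <- c(nwu = as.numeric(ip_nwu))
  if (set %in% c("nwu_clinical", "nwu_clinical_imaging")) {
    if (is.null(clinical))
      stop("clinical covariates (age, gender, nihss) required for set '",
           set, "'")
    g <- clinical$gender
    if (is.character(g) || is.factor(g)) g <- as.integer(g == "female")
    out <- c(out, age = as.numeric(clinical$age), gender = as.numeric(g),
             nihss = as.numeric(clinical$nihss))
  }
  if (set %in% c("nwu_imaging", "nwu_clinical_imaging")) {
    if (is.null(hist)) stop("histogram required for set '", set, "'")
    stopifnot(inherits(hist, "nwu_histogram"))
    y <- hist$counts
    imaging <- c(stats::setNames(as.numeric(y),
                                 paste0("y", seq_along(y))),
                 std = sqrt(mean((y - mean(y))^2)),
                 slope = histogram_slope(y),
                 entropy = histogram_entropy(hist$proportions),
                 skewness = as.numeric(vector_skewness(y)),
                 kurtosis = as.numeric(vector_kurtosis(y)))
    out <- c(out, imaging)
  }
  out
}

#' Full feature table for a synthetic cohort
#'
#' Runs the patch pipeline on every subject of a [generate_cohort()]
#' cohort: places the default mirrored patches, measures pooled IP-NWU,
#' builds the voxel-wise ratio maps and histogram, and assembles the
#' requested feature set, alongside the SR-NWU computed from the true
#' lesion mask.
#'
#' @param cohort a `ct_cohort`.
#' @param set feature set passed to [assemble_features()].
#' @param n_pairs,jitter passed to [phantom_patch_specs()].
#' @return data.frame: subject_id, mce, true_w, ip_nwu, sr_nwu, then the
#'   feature columns.
#' @export
cohort_features <- function(cohort, set = "nwu_clinical_imaging",
                            n_pairs = 4, jitter = 0) {
  stopifnot(inherits(cohort, "ct_cohort"))
  rows <- lapply(cohort, function(subj) {
    specs <- phantom_patch_specs(subj$phantom, n_pairs = n_pairs,
                                 jitter = jitter)
    m <- measure_ip_nwu(subj$volume, specs, declared_side = subj$lesion_side)
    hist <- build_histogram(m$ratio_maps)
    fv <- assemble_features(hist, ip_nwu = m$nwu$ip_nwu,
                            clinical = subj$record, set = set)
    sr <- compute_sr_nwu(subj$volume, subj$lesion_mask)
    cbind(subj$record[c("subject_id", "mce", "true_w")],
          ip_nwu = m$nwu$ip_nwu, sr_nwu = sr$sr_nwu,
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}
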