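#' Unit cell
#'
#' Construct a crystallographic unit cell. Lengths in Angstrom, angles in
#' degrees. Validity requires positive lengths, angles in (0, 180) and a
#' positive metric-tensor determinant (the three angles must close a real
#' parallelepiped).
#'
#' @param a,b,c Cell edge lengths (Angstrom), > 0.
#' @param alpha,beta,gamma Cell angles (degrees), each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(79, 79, 38, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (det(metric_tensor(cell)) <= 0)
    stop("unit cell angles are geometrically inconsistent (non-positive metric determinant)")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g (A)  alpha=%.4g beta=%.4g gamma=%.4g (deg)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# Direct-space metric tensor G_ij = a_i . a_j
metric_tensor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(a * a,       a * b * cg, a * c * cb,
                      a * b * cg,  b * b,      b * c * ca,
                      a * c * cb,  b * c * ca, c * c), 3, 3))
}

#' d-spacing of a reflection
#'
#' Resolution of Miller index (h,k,l) in a given unit cell, from the
#' reciprocal metric tensor: 1/d^2 = m' G* m with G* the inverse of the
#' direct metric tensor. Vectorized over rows of the index input.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or a 3-column matrix / data frame
#'   of Miller indices (one per row).
#' @return d-spacing(s) in Angstrom.
#' @examples
#' compute_d_spacing(unit_cell(10, 10, 10), c(1, 0, 0))  # 10
#' @export
compute_d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- if (is.matrix(hkl) || is.data.frame(hkl)) as.matrix(hkl) else matrix(hkl, ncol = 3)
  if (ncol(m) != 3) stop("hkl must have 3 columns")
  if (any(rowSums(m != 0) == 0)) stop("(0,0,0) has no d-spacing")
  gstar <- solve(metric_tensor(cell))
  inv_d2 <- rowSums((m %*% gstar) * m)
  drop(1 / sqrt(inv_d2))
}

#' Unmerged reflection table
#'
#' The central container: one row per observation of a symmetry-reduced
#' Miller index on one lattice, plus one record per lattice carrying its
#' Pearson correlation `cc` to the scaling reference. Input is assumed
#' already scaled and symmetry-reduced; negative intensities are legitimate
#' (weak reflections after background subtraction) but sigmas must be
#' positive and finite.
#'
#' @param observations data.frame with columns `h, k, l, lattice_id,
#'   intensity, sigma` and optionally `d_spacing`.
#' @param lattices Optional data.frame with columns `lattice_id, cc` and
#'   optionally `n_obs`. If `NULL`, records are synthesized with `cc = NA`
#'   (correlations can be filled in later with [lattice_correlations()]).
#' @param drop_invalid Drop rows with non-positive or non-finite sigma
#'   (default `TRUE`); the number dropped is reported via a message and the
#'   `"n_dropped"` attribute.
#' @return A `refl_table`: list with data.tables `observations` (sorted by
#'   h, k, l, lattice_id, input order) and `lattices`.
#' @export
refl_table <- function(observations, lattices = NULL, drop_invalid = TRUE) {
  obs <- as.data.table(observations)
  req <- c("h", "k", "l", "lattice_id", "intensity", "sigma")
  miss <- setdiff(req, names(obs))
  if (length(miss))
    stop("missing required observation column(s): ", paste(miss, collapse = ", "))
  if (!"d_spacing" %in% names(obs)) obs[, d_spacing := NA_real_]
  obs <- obs[, c(req, "d_spacing"), with = FALSE]
  obs[, `:=`(h = as.integer(h), k = as.integer(k), l = as.integer(l),
             lattice_id = as.character(lattice_id),
             intensity = as.numeric(intensity), sigma = as.numeric(sigma),
             d_spacing = as.numeric(d_spacing))]
  if (any(!is.finite(obs$intensity)))
    stop("non-finite intensity encountered")
  bad <- !is.finite(obs$sigma) | obs$sigma <= 0
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    if (!drop_invalid) stop(n_dropped, " observation(s) have non-positive or non-finite sigma")
    message("dropping ", n_dropped, " observation(s) with non-positive or non-finite sigma")
    obs <- obs[!bad]
  }
  # canonical total order: value tie-breaks (not input position) so that
  # any row permutation of the same data yields the identical table, which
  # downstream deterministic subsampling relies on
  setorder(obs, h, k, l, lattice_id, intensity, sigma)

  if (is.null(lattices)) {
    lat <- obs[, .(n_obs = .N), by = lattice_id]
    lat[, cc := NA_real_]
  } else {
    lat <- as.data.table(lattices)
    if (!all(c("lattice_id", "cc") %in% names(lat)))
      stop("missing required lattice column(s): ",
           paste(setdiff(c("lattice_id", "cc"), names(lat)), collapse = ", "))
    lat[, `:=`(lattice_id = as.character(lattice_id), cc = as.numeric(cc))]
    counts <- obs[, .(n_obs = .N), by = lattice_id]
    orphan <- setdiff(unique(obs$lattice_id), lat$lattice_id)
    if (length(orphan))
      stop("observations reference lattice(s) without a record: ",
           paste(head(orphan, 5), collapse = ", "))
    lat <- merge(lat[, .(lattice_id, cc)], counts, by = "lattice_id", all.x = TRUE)
    lat[is.na(n_obs), n_obs := 0L]
    if (any(!is.na(lat$cc) & abs(lat$cc) > 1))
      stop("lattice cc outside [-1, 1]")
  }
  setorder(lat, lattice_id)
  setcolorder(lat, c("lattice_id", "cc", "n_obs"))
  out <- structure(list(observations = obs[], lattices = lat[]),
                   class = "refl_table")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.refl_table <- function(x, ...) {
  cat(sprintf("<refl_table> %d observations, %d unique Miller indices, %d lattices\n",
              nrow(x$observations),
              nrow(unique(x$observations[, .(h, k, l)])),
              nrow(x$lattices)))
  invisible(x)
}

#' Number of observations in a reflection table
#' @param table A `refl_table`.
#' @return Integer count.
#' @export
n_observations <- function(table) nrow(table$observations)

# 17 significant digits: lossless double round-trip
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

read_tsv_commented <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data in ", path)
  has_lat <- "lattice_id" %in% strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fread(text = paste(lines, collapse = "\n"), sep = "\t", header = TRUE,
        colClasses = if (has_lat) list(character = "lattice_id"),
        na.strings = "NA")
}

#' Read an unmerged reflection table from TSV
#'
#' Native on-disk format: UTF-8 tab-separated values with a header row;
#' lines starting with `#` are comments. The reflection file has columns
#' `h k l lattice_id intensity sigma [d_spacing]`; the optional lattice
#' file has `lattice_id cc [n_obs]`. Rows with non-positive or non-finite
#' sigma are dropped with a reported count. The returned table is in
#' canonical deterministic order.
#'
#' @param reflections Path to the reflections TSV.
#' @param lattices Optional path to the lattices TSV.
#' @return A [refl_table()]. The `"n_dropped"` attribute reports rejected rows.
#' @export
read_unmerged_table <- function(reflections, lattices = NULL) {
  if (!file.exists(reflections)) stop("file not found: ", reflections)
  obs <- read_tsv_commented(reflections)
  lat <- NULL
  if (!is.null(lattices)) {
    if (!file.exists(lattices)) stop("file not found: ", lattices)
    lat <- read_tsv_commented(lattices)
  }
  refl_table(obs, lat)
}

#' Write an unmerged reflection table to TSV
#'
#' Byte-deterministic: fixed column order, floats at 17 significant digits
#' (lossless round trip), `\n` line endings.
#'
#' @param table A [refl_table()].
#' @param reflections Output path for the reflections TSV.
#' @param lattices Optional output path for the lattices TSV.
#' @return Invisibly, the reflections path.
#' @export
write_unmerged_table <- function(table, reflections, lattices = NULL) {
  stopifnot(inherits(table, "refl_table"))
  obs <- table$observations
  has_d <- any(is.finite(obs$d_spacing))
  cols <- c("h", "k", "l", "lattice_id", "intensity", "sigma",
            if (has_d) "d_spacing")
  body <- c(paste(cols, collapse = "\t"),
            if (nrow(obs)) do.call(paste, c(list(sep = "\t"), lapply(cols, function(cl) {
              v <- obs[[cl]]
              if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v)
            }))))
  con <- file(reflections, open = "wb")
  writeLines(body, con, sep = "\n", useBytes = TRUE)
  close(con)
  if (!is.null(lattices)) {
    lat <- table$lattices
    lbody <- c("lattice_id\tcc\tn_obs",
               if (nrow(lat)) paste(lat$lattice_id, fmt_num(lat$cc), lat$n_obs, sep = "\t"))
    con <- file(lattices, open = "wb")
    writeLines(lbody, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(reflections)
}

#' Group observations by Miller index
#'
#' Every observation belongs to exactly one group keyed by its exact
#' (h, k, l); the group mean is the plain all-in arithmetic mean of the
#' member intensities.
#'
#' @param table A [refl_table()].
#' @return data.table with one row per Miller index: `h, k, l, n`
#'   (multiplicity), `mean_intensity`, `d_spacing` (first finite member
#'   value), ordered like the table.
#' @export
group_by_miller <- function(table) {
  stopifnot(inherits(table, "refl_table"))
  table$observations[, .(
    n = .N,
    mean_intensity = mean(intensity),
    d_spacing = d_spacing[which(is.finite(d_spacing))[1]]
  ), by = .(h, k, l)]
}

# Attach per-observation group statistics used by both calibrations:
# group id, multiplicity n, all-in mean <I_h>.
annotate_groups <- function(table) {
  obs <- copy(table$observations)
  obs[, group_id := .GRP, by = .(h, k, l)]
  obs[, `:=`(n = .N, mean_intensity = mean(intensity)), by = group_id]
  obs[, cc := table$lattices$cc[match(lattice_id, table$lattices$lattice_id)]]
  obs[]
}
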