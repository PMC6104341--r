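#' Creep curve container
#'
#' A time-ordered strain trace recorded under constant stress, with optional
#' acquisition metadata. Strain is dimensionless engineering strain
#' (deformation / initial sample height).
#'
#' @param time numeric time vector in seconds, non-negative; sorted
#'   internally, duplicate times collapsed by mean.
#' @param strain numeric strain vector, finite, same length as \code{time};
#'   at least 4 points.
#' @param stress optional constant applied stress in Pa.
#' @param group optional group label (e.g. rice type).
#' @param metadata optional list (probe diameter, sample height, applied
#'   force, generating truth, ...).
#' @return object of class \code{"creep_curve"}.
#' @export
creep_curve <- function(time, strain, stress = NULL, group = NULL,
                        metadata = list()) {
  if (!is.numeric(time) || !is.numeric(strain))
    stop("time and strain must be numeric", call. = FALSE)
  if (length(time) != length(strain))
    stop("time and strain lengths differ", call. = FALSE)
  if (anyNA(time) || anyNA(strain) || any(!is.finite(strain)))
    stop("time and strain must be finite", call. = FALSE)
  ord <- order(time)
  time <- time[ord]; strain <- strain[ord]
  if (anyDuplicated(time)) {
    strain <- as.numeric(tapply(strain, time, mean))
    time <- sort(unique(time))
  }
  if (length(time) < 4)
    stop("a creep curve needs at least 4 distinct time points", call. = FALSE)
  if (time[1] < 0) stop("time must be non-negative", call. = FALSE)
  if (!is.null(stress)) stopifnot(is.numeric(stress), stress > 0)
  structure(list(time = time, strain = strain, stress = stress,
                 group = group, metadata = metadata),
            class = "creep_curve")
}

#' @export
print.creep_curve <- function(x, ...) {
  cat("Creep curve: ", length(x$time), " points, t = ", min(x$time), "-",
      max(x$time), " s, strain ", signif(min(x$strain), 4), "-",
      signif(max(x$strain), 4), "\n", sep = "")
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  if (!is.null(x$stress)) cat("  stress:", signif(x$stress, 5), "Pa\n")
  invisible(x)
}

#' Compression-rig geometry
#'
#' Geometry and load of the cylindrical compression creep rig: a flat
#' cylindrical probe pressing a sample held in a slightly wider cylindrical
#' cavity. Defaults mirror a 30-mm probe in a 35-mm, 20-mm-deep cavity
#' loaded to 20 N.
#'
#' @param probe_diameter probe diameter, mm.
#' @param cavity_diameter cavity diameter, mm; at least the probe diameter.
#' @param sample_height initial sample height, mm (strain normalization
#'   basis).
#' @param applied_force constant applied force, N.
#' @return list of class \code{"creep_geometry"}.
#' @export
creep_geometry <- function(probe_diameter = 30, cavity_diameter = 35,
                           sample_height = 20, applied_force = 20) {
  stopifnot(probe_diameter > 0, cavity_diameter > 0, sample_height > 0,
            applied_force > 0)
  if (probe_diameter > cavity_diameter)
    stop("probe diameter exceeds cavity diameter", call. = FALSE)
  structure(list(probe_diameter = probe_diameter,
                 cavity_diameter = cavity_diameter,
                 sample_height = sample_height,
                 applied_force = applied_force),
            class = "creep_geometry")
}

#' Constant stress from rig geometry
#'
#' \eqn{\sigma_0 = F / (\pi d^2 / 4)} with the probe diameter \eqn{d}
#' converted to metres; stress in Pa. Valid because the compression area
#' stays approximately constant during the hold.
#'
#' @param geometry a \code{\link{creep_geometry}}.
#' @return stress in Pa.
#' @export
geometry_stress <- function(geometry) {
  stopifnot(inherits(geometry, "creep_geometry"))
  d_m <- geometry$probe_diameter / 1000
  geometry$applied_force / (pi * d_m^2 / 4)
}

.sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1)
  counts <- c(`,` = lengths(regmatches(l1, gregexpr(",", l1, fixed = TRUE))),
              `\t` = lengths(regmatches(l1, gregexpr("\t", l1, fixed = TRUE))),
              `;` = lengths(regmatches(l1, gregexpr(";", l1, fixed = TRUE))))
  if (all(counts == 0)) stop("cannot detect delimiter (comma/tab/semicolon) ",
                             "in ", path, call. = FALSE)
  names(counts)[which.max(counts)]
}

#' Read a creep trace from delimited text
#'
#' Reads a CSV/TSV (delimiter auto-detected among comma, tab, semicolon),
#' maps columns via \code{column_map}, sorts by time and collapses duplicate
#' times by mean. If a strain column is mapped, the result is a ready
#' \code{\link{creep_curve}}; if force/deformation columns are mapped
#' instead, the result is a raw trace (class \code{"creep_trace"}) awaiting
#' \code{\link{to_stress_strain}}.
#'
#' @param path file path.
#' @param column_map named character vector mapping roles to file column
#'   names; roles: \code{time} (required; seconds), and either \code{strain}
#'   or both \code{force} (N) and \code{deformation} (mm). Default
#'   \code{c(time = "time_s", strain = "strain")}.
#' @param group optional group label.
#' @return a \code{creep_curve} or a \code{creep_trace} data.frame.
#' @export
read_creep_curve <- function(path,
                             column_map = c(time = "time_s",
                                            strain = "strain"),
                             group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) < 4)
    stop("need at least 4 data rows, got ", nrow(df), " in ", path,
         call. = FALSE)
  if (!"time" %in% names(column_map))
    stop("column_map must map 'time'", call. = FALSE)
  has_strain <- "strain" %in% names(column_map)
  has_fd <- all(c("force", "deformation") %in% names(column_map))
  if (!has_strain && !has_fd)
    stop("column_map must map 'strain', or both 'force' and 'deformation'",
         call. = FALSE)
  miss <- setdiff(unname(column_map), names(df))
  if (length(miss))
    stop("column(s) not in file: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cm in unname(column_map)) {
    v <- suppressWarnings(as.numeric(df[[cm]]))
    bad <- which(is.na(v) & !is.na(df[[cm]]))
    if (length(bad))
      stop("non-numeric value in column '", cm, "', data row ", bad[1],
           call. = FALSE)
    if (anyNA(v)) stop("missing value in column '", cm, "'", call. = FALSE)
    df[[cm]] <- v
  }
  if (has_strain) {
    creep_curve(df[[column_map[["time"]]]], df[[column_map[["strain"]]]],
                group = group, metadata = list(source = path))
  } else {
    out <- data.frame(time = df[[column_map[["time"]]]],
                      force = df[[column_map[["force"]]]],
                      deformation = df[[column_map[["deformation"]]]])
    out <- out[order(out$time), ]
    if (anyDuplicated(out$time))
      out <- stats::aggregate(cbind(force, deformation) ~ time, out, mean)
    rownames(out) <- NULL
    attr(out, "source") <- path
    attr(out, "group") <- group
    class(out) <- c("creep_trace", "data.frame")
    out
  }
}

#' Convert a force/deformation trace to a stress/strain creep curve
#'
#' Engineering strain = deformation / initial sample height; constant stress
#' from \code{\link{geometry_stress}}. The creep clock starts at the
#' constant-force hold: samples before the force first reaches
#' \code{hold_tol} of its maximum (the loading ramp) are dropped and time is
#' re-zeroed at the first hold sample.
#'
#' @param trace a \code{creep_trace} from \code{\link{read_creep_curve}}, or
#'   a data.frame with columns \code{time}, \code{deformation} and
#'   optionally \code{force}.
#' @param geometry a \code{\link{creep_geometry}}.
#' @param hold_tol relative tolerance defining the force plateau (default
#'   0.01: first sample within 1\% of the maximum force).
#' @return a \code{\link{creep_curve}} with stress set.
#' @export
to_stress_strain <- function(trace, geometry = creep_geometry(),
                             hold_tol = 0.01) {
  stopifnot(is.data.frame(trace), inherits(geometry, "creep_geometry"))
  if (!all(c("time", "deformation") %in% names(trace)))
    stop("trace needs 'time' and 'deformation' columns", call. = FALSE)
  if (any(trace$deformation >= geometry$sample_height))
    stop("deformation reaches the sample height (", geometry$sample_height,
         " mm): physically invalid", call. = FALSE)
  if ("force" %in% names(trace) && nrow(trace) > 0) {
    fmax <- max(trace$force)
    i0 <- which(trace$force >= (1 - hold_tol) * fmax)[1]
    trace <- trace[i0:nrow(trace), ]
  }
  creep_curve(trace$time - trace$time[1],
              trace$deformation / geometry$sample_height,
              stress = geometry_stress(geometry),
              group = attr(trace, "group"),
              metadata = list(probe_diameter_mm = geometry$probe_diameter,
                              sample_height_mm = geometry$sample_height,
                              applied_force_N = geometry$applied_force))
}

#' Write a creep curve as CSV
#'
#' Canonical two-column CSV (\code{time_s,strain}); values formatted with 12
#' significant digits so a write-read-write cycle is byte-stable. When the
#' curve carries a generating truth (synthetic curves), a JSON sidecar
#' \code{<path>.truth.json} is written alongside.
#'
#' @param curve a \code{\link{creep_curve}}.
#' @param path output CSV path.
#' @param sidecar write the truth sidecar when available (default TRUE).
#' @return the path, invisibly.
#' @export
write_creep_curve <- function(curve, path, sidecar = TRUE) {
  stopifnot(inherits(curve, "creep_curve"))
  lines <- c("time_s,strain",
             paste(sprintf("%.12g", curve$time),
                   sprintf("%.12g", curve$strain), sep = ","))
  writeLines(lines, path)
  if (sidecar && !is.null(curve$metadata$truth))
    jsonlite::write_json(curve$metadata$truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
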