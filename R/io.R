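.dimerlab_header <- function(seed = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("dimerlab")),
                error = function(e) "dev")
  paste0("# dimerlab ", v,
         if (!is.null(seed)) paste0("; seed=", seed) else "")
}

#' Write and read force-curve datasets
#'
#' Curves are stored as two-column tab-separated files
#' (`extension_nm`, `force_pN`), one per curve, next to a `manifest.csv`
#' recording filename, pulling speed, spring constant and sampling rate.
#'
#' @param curves list of [force_curve()] objects.
#' @param dir output directory (created if missing).
#' @param seed optional seed recorded in file headers.
#' @return `write_force_curves` returns the manifest invisibly;
#'   `read_force_curves` returns the list of curves.
#' @export
write_force_curves <- function(curves, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .dimerlab_header(seed)
  man <- do.call(rbind, lapply(curves, function(cv) {
    fn <- paste0(cv$id, ".tsv")
    con <- file(file.path(dir, fn), "w")
    writeLines(c(hdr, "extension_nm\tforce_pN"), con)
    utils::write.table(data.frame(cv$extension, cv$force), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    close(con)
    data.frame(filename = fn, pulling_speed_nm_s = cv$v,
               spring_constant_pN_nm = cv$kc, sampling_rate_hz = cv$sampling_rate,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname write_force_curves
#' @export
read_force_curves <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.table(file.path(dir, man$filename[i]), header = TRUE,
                           sep = "\t", comment.char = "#")
    force_curve(d[[1]], d[[2]], v = man$pulling_speed_nm_s[i],
                kc = man$spring_constant_pN_nm[i],
                sampling_rate = man$sampling_rate_hz[i],
                id = sub("\\.tsv$", "", man$filename[i]))
  })
}

#' Write and read sedimentation-equilibrium radial scans
#'
#' CSV with columns `radius_cm`, `absorbance_AU`; a comment header carries
#' the rotor speed (rpm), wavelength, temperature and column geometry.
#'
#' @param scan a `radial_scan` (see [make_se_scans()]).
#' @param path file path.
#' @param wavelength_nm detection wavelength recorded in the header.
#' @param seed optional seed recorded in the header.
#' @export
write_radial_scan <- function(scan, path, wavelength_nm = 280, seed = NULL) {
  stopifnot(inherits(scan, "radial_scan"))
  con <- file(path, "w")
  writeLines(c(.dimerlab_header(seed),
               sprintf("# rpm=%g wavelength_nm=%g T_K=%g meniscus_cm=%g bottom_cm=%g",
                       scan$rpm, wavelength_nm, scan$T_K, scan$meniscus,
                       scan$bottom),
               "radius_cm,absorbance_AU"), con)
  utils::write.table(data.frame(scan$r, scan$A), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_radial_scan
#' @export
read_radial_scan <- function(path) {
  lines <- readLines(path)
  meta_line <- grep("^# rpm=", lines, value = TRUE)[1]
  get_val <- function(key) {
    m <- regmatches(meta_line, regexpr(paste0(key, "=[0-9.eE+-]+"), meta_line))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  d <- utils::read.csv(path, comment.char = "#")
  rpm <- get_val("rpm")
  structure(list(r = d[[1]], A = d[[2]], rpm = rpm,
                 omega = rpm_to_omega(rpm), T_K = get_val("T_K"),
                 meniscus = get_val("meniscus_cm"),
                 bottom = get_val("bottom_cm")),
            class = "radial_scan")
}

#' Write and read SAXS profiles
#'
#' Whitespace-delimited three-column `.dat` files (`q`, `I`, `sigma`)
#' with `#` comments, the layout consumed by standard indirect-transform
#' tools. q is stored in nm^-1; on reading, `units = "angstrom"` converts
#' Angstrom^-1 input to nm^-1 (flagged in the returned metadata).
#'
#' @param profile a [saxs_profile()].
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @export
write_saxs_profile <- function(profile, path, seed = NULL) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  writeLines(c(.dimerlab_header(seed), "# q_nm^-1  I  sigma"), con)
  utils::write.table(data.frame(profile$q, profile$I, profile$sigma), con,
                     sep = "  ", row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_saxs_profile
#' @param units `"nm"` (default) or `"angstrom"` for the q column of the
#'   file being read.
#' @export
read_saxs_profile <- function(path, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  d <- utils::read.table(path, comment.char = "#")
  q <- d[[1]]
  converted <- FALSE
  if (units == "angstrom") {
    q <- q * 10
    converted <- TRUE
  }
  sig <- if (ncol(d) >= 3) d[[3]] else rep(1, length(q))
  saxs_profile(q, d[[2]], sig,
               metadata = list(source = path, converted_from_angstrom = converted))
}

#' Write and read FRET intensity traces
#'
#' One CSV per trace (`time_s`, `donor`, `acceptor`) plus a
#' `traces_manifest.csv` with the per-channel backgrounds.
#'
#' @param traces list of [fret_trace()] objects.
#' @param dir directory.
#' @param seed optional seed recorded in headers.
#' @export
write_fret_traces <- function(traces, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .dimerlab_header(seed)
  man <- do.call(rbind, lapply(traces, function(tr) {
    fn <- paste0(tr$id, ".csv")
    con <- file(file.path(dir, fn), "w")
    writeLines(c(hdr, "time_s,donor,acceptor"), con)
    utils::write.table(data.frame(tr$time, tr$donor, tr$acceptor), con,
                       sep = ",", row.names = FALSE, col.names = FALSE)
    close(con)
    data.frame(filename = fn, bg_donor = tr$bg_donor,
               bg_acceptor = tr$bg_acceptor, stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(dir, "traces_manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname write_fret_traces
#' @export
read_fret_traces <- function(dir) {
  man <- utils::read.csv(file.path(dir, "traces_manifest.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.csv(file.path(dir, man$filename[i]), comment.char = "#")
    fret_trace(d[[1]], d[[2]], d[[3]], bg_donor = man$bg_donor[i],
               bg_acceptor = man$bg_acceptor[i],
               id = sub("\\.csv$", "", man$filename[i]))
  })
}

#' Write and read polarized anisotropy decays
#'
#' CSV with columns `time_ns`, `I_par`, `I_perp`; the G factor is carried
#' in a comment header.
#'
#' @param decay a [polarized_decay()].
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @export
write_polarized_decay <- function(decay, path, seed = NULL) {
  stopifnot(inherits(decay, "polarized_decay"))
  con <- file(path, "w")
  writeLines(c(.dimerlab_header(seed), sprintf("# G=%g", decay$G),
               "time_ns,I_par,I_perp"), con)
  utils::write.table(data.frame(decay$t, decay$I_parallel, decay$I_perpendicular),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_polarized_decay
#' @export
read_polarized_decay <- function(path) {
  lines <- readLines(path, n = 5)
  gline <- grep("^# G=", lines, value = TRUE)
  G <- if (length(gline)) as.numeric(sub("^# G=", "", gline[1])) else 1
  d <- utils::read.csv(path, comment.char = "#")
  polarized_decay(d[[1]], d[[2]], d[[3]], G = G)
}
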