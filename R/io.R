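#' Read / write contact matrices
#'
#' Dense tab-separated values with bin labels as header row and first
#' column: the interchange format for loci up to a few thousand bins.
#' Values round-trip to 9 significant digits; symmetry is enforced on read
#' (maximum relative asymmetry 1e-6). An HDF5 backend is not available in
#' this build and raises a not-supported error.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"hdf5"` (stub).
#' @return `read_contact_matrix`: an `sbs_contact_matrix` with bin labels as
#'   dimnames.
#' @export
read_contact_matrix <- function(path, format = c("tsv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("not-supported: HDF5 backend not available; use dense TSV")
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("format: matrix is not square")
  if (any(is.na(m))) stop("format: NaN/NA entries")
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > 1e-6 * scale)
    stop("format: asymmetry beyond tolerance 1e-6")
  m <- (m + t(m)) / 2
  new_contact_matrix(m)
}

#' @rdname read_contact_matrix
#' @param m matrix to write (labels taken from dimnames, else `bin_<i>`).
#' @export
write_contact_matrix <- function(m, path, format = c("tsv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("not-supported: HDF5 backend not available; use dense TSV")
  v <- unclass(m)
  if (is.null(rownames(v)))
    dimnames(v) <- list(paste0("bin_", seq_len(nrow(v)) - 1L),
                        paste0("bin_", seq_len(ncol(v)) - 1L))
  df <- data.frame(bin = rownames(v), signif(v, 9), check.names = FALSE)
  colnames(df) <- c("bin", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write contact-decay curves
#'
#' Two- or three-column TSV: `s`, `p`, optional `n_pairs`.
#'
#' @param path file path.
#' @param units separation units recorded on the curve.
#' @return an `sbs_ps_curve`.
#' @export
read_ps_curve <- function(path, units = "bp") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ps_curve(df$s, df$p,
           if ("n_pairs" %in% names(df)) df$n_pairs else rep(NA_real_, nrow(df)),
           units = units)
}

#' @rdname read_ps_curve
#' @param curve an `sbs_ps_curve`.
#' @export
write_ps_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a pure-state library as TSV
#'
#' Long format: columns `state`, `s`, `p`.
#'
#' @param path file path.
#' @return an `sbs_state_library`.
#' @export
read_state_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  curves <- lapply(split(df, df$state), function(d)
    new_ps_curve(d$s, d$p))
  new_state_library(curves)
}

#' @rdname read_state_library
#' @param library an `sbs_state_library`.
#' @export
write_state_library <- function(library, path) {
  df <- do.call(rbind, lapply(names(library$curves), function(nm)
    data.frame(state = nm, s = library$curves[[nm]]$s,
               p = library$curves[[nm]]$p)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a binding profile as BED
#'
#' One BED line per maximal run of constant (colour, multiplicity);
#' 0-based half-open genomic intervals, colour in the name field
#' (`color<k>`), multiplicity in the score field. Inert beads produce no
#' lines.
#'
#' @param profile an `sbs_binding_profile`.
#' @param path output path (`.bed`).
#' @param bin_bp genomic span of one bead (bp).
#' @param chrom chromosome name.
#' @param origin_bp genomic start of bead 0.
#' @return the path, invisibly.
#' @export
write_binding_profile_bed <- function(profile, path, bin_bp = 4e4,
                                      chrom = "chr1", origin_bp = 0) {
  m <- profile$multiplicities
  rows <- list()
  for (cc in seq_len(ncol(m))) {
    v <- m[, cc]
    r <- rle(v)
    at <- 0
    for (k in seq_along(r$lengths)) {
      if (r$values[k] > 0)
        rows[[length(rows) + 1]] <- data.frame(
          start = origin_bp + at * bin_bp,
          end = origin_bp + (at + r$lengths[k]) * bin_bp,
          name = paste0("color", cc), score = r$values[k])
      at <- at + r$lengths[k]
    }
  }
  if (length(rows) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      name = df$name, score = df$score)
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Import a binding profile from BED
#'
#' Inverse of [write_binding_profile_bed()] for profiles written by it.
#'
#' @param path BED path.
#' @param n_beads chain length.
#' @param n_colors number of colours.
#' @inheritParams write_binding_profile_bed
#' @param ... passed to [binding_profile()].
#' @return an `sbs_binding_profile`.
#' @export
read_binding_profile_bed <- function(path, n_beads, n_colors, bin_bp = 4e4,
                                     origin_bp = 0, ...) {
  gr <- rtracklayer::import(path, format = "BED")
  m <- matrix(0L, n_beads, n_colors)
  if (length(gr) > 0) {
    start <- (GenomicRanges::start(gr) - 1 - origin_bp) / bin_bp
    end <- GenomicRanges::end(gr) / bin_bp - origin_bp / bin_bp
    col <- as.integer(sub("^color", "", gr$name))
    for (k in seq_along(gr)) {
      idx <- seq.int(start[k] + 1L, end[k])
      m[idx, col[k]] <- as.integer(gr$score[k])
    }
  }
  binding_profile(m, ...)
}

#' Write / read trajectories as multi-frame XYZ
#'
#' Standard XYZ: per frame an atom-count line, a comment line carrying
#' `time=<tau> box=<edge>`, then one line per particle with an element tag
#' encoding particle kind and colour (`B<dominant colour>` for beads, 0 =
#' inert; `S<colour>` for binders). Positions round-trip to 6 decimals.
#'
#' @param traj an `sbs_trajectory`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  n <- dim(traj$beads)[1]; m <- dim(traj$binders)[1]
  S <- dim(traj$beads)[3]
  mult <- traj$system$chain$colors
  dom <- max.col(mult, ties.method = "first")
  dom[rowSums(mult) == 0] <- 0L
  tags <- c(paste0("B", dom),
            if (m > 0) paste0("S", traj$system$binder_colors))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(S)) {
    pos <- rbind(if (n > 0) traj$beads[, , t, drop = TRUE],
                 if (m > 0) traj$binders[, , t, drop = TRUE])
    writeLines(as.character(n + m), con)
    writeLines(sprintf("time=%.6f box=%.6f", traj$times[t],
                       traj$system$box$edge), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", tags, pos[, 1], pos[, 2],
                       pos[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @return `read_trajectory_xyz`: list with `positions` (P x 3 x S array),
#'   `tags`, `times`, `box_edge`.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); box <- NA_real_
  at <- 1
  tags <- NULL
  while (at <= length(lines)) {
    p <- as.integer(lines[at])
    meta <- lines[at + 1]
    times <- c(times, as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", meta)))
    box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", meta))
    body <- lines[at + 1 + seq_len(p)]
    parts <- strsplit(body, " +")
    tags <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(v) as.numeric(v[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    at <- at + 2 + p
  }
  arr <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  list(positions = arr, tags = tags, times = times, box_edge = box)
}

#' Write / read binding profiles as TSV
#'
#' Long format: `bead` (0-based), `color`, `multiplicity`; header comment
#' lines `#n_beads=`, `#n_colors=`, `#e_int=`, `#concentration=` keep the
#' profile self-describing.
#'
#' @param profile an `sbs_binding_profile`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_binding_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#n_beads=%d", profile$n_beads),
               sprintf("#n_colors=%d", profile$n_colors),
               sprintf("#e_int=%s", paste(profile$e_int, collapse = ",")),
               sprintf("#concentration=%s",
                       paste(profile$concentration, collapse = ","))), con)
  idx <- which(profile$multiplicities > 0, arr.ind = TRUE)
  df <- data.frame(bead = idx[, 1] - 1L, color = idx[, 2],
                   multiplicity = profile$multiplicities[idx])
  df <- df[order(df$bead, df$color), ]
  writeLines("bead\tcolor\tmultiplicity", con)
  if (nrow(df) > 0)
    writeLines(sprintf("%d\t%d\t%d", df$bead, df$color, df$multiplicity), con)
  invisible(path)
}

#' @rdname write_binding_profile_tsv
#' @export
read_binding_profile_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^#", key, "="), "",
                           grep(paste0("^#", key, "="), hdr, value = TRUE))
  n <- as.integer(get("n_beads")); nc <- as.integer(get("n_colors"))
  e_int <- as.numeric(strsplit(get("e_int"), ",")[[1]])
  conc <- as.numeric(strsplit(get("concentration"), ",")[[1]])
  body <- lines[!grepl("^#", lines)]
  m <- matrix(0L, n, nc)
  if (length(body) > 1) {
    df <- utils::read.table(text = body, header = TRUE, sep = "\t")
    if (nrow(df) > 0)
      m[cbind(df$bead + 1L, df$color)] <- as.integer(df$multiplicity)
  }
  binding_profile(m, e_int = e_int, concentration = conc,
                  m_max = max(3, m))
}
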