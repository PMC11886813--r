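#' Structure input/output and dataset filtering
#'
#' Reading goes through bio3d (PDB via `read.pdb`, mmCIF via `read.cif`):
#' first model only, altloc conflicts resolved by highest occupancy then
#' label order, heavy atoms mapped into atom14 slots by name, HETATM
#' records skipped, unknown residue types kept as `UNK` (extra one-hot
#' class, no chi angles). Writing emits PDB through bio3d or a minimal
#' mmCIF `atom_site` loop (no mmCIF writer exists in the installed stack);
#' structures with more than 62 chains fall back to mmCIF automatically
#' since the PDB chain column is a single character.
#'
#' Dataset filtering follows the standard curation rules for side-chain
#' packing corpora: drop residues missing any of N/CA/C, drop the later of
#' any C-alpha pair closer than a tolerance, then reject structures that
#' are shorter than 40 residues or more than 25% unknown.
#'
#' @name structure_io
#' @keywords internal
NULL

#' Dataset filter configuration
#'
#' @param min_residues minimum residues after cleaning (default 40).
#' @param max_unknown_fraction maximum fraction of unknown residues
#'   (default 0.25).
#' @param ca_clash_tolerance C-alpha pairs closer than this are considered
#'   overlapping (Angstrom, default 1e-3).
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(min_residues = 40, max_unknown_fraction = 0.25,
                          ca_clash_tolerance = 1e-3) {
  structure(list(min_residues = min_residues,
                 max_unknown_fraction = max_unknown_fraction,
                 ca_clash_tolerance = ca_clash_tolerance),
            class = "filter_config")
}

#' Read a structure from PDB or mmCIF
#'
#' @param path input file; format inferred from the extension unless given.
#' @param format `"pdb"`, `"cif"`, or `"auto"`.
#' @return a [chi_structure()] carrying author residue numbers in `resno`;
#'   insertion codes, where present, are appended to `resno` metadata via
#'   the `insert` attribute.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif"
    else "pdb"
  }
  pdb <- if (format == "cif") bio3d::read.cif(path) else {
    # keep altloc records; conflicts are resolved below by occupancy
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (any(pdb$atom$type == "HETATM")) {
    het_ch <- setdiff(unique(pdb$atom$chain[pdb$atom$type == "HETATM"]),
                      unique(at$chain))
    if (length(het_ch)) {
      warning("skipping HETATM-only chain(s): ",
              paste(het_ch, collapse = ", "))
    }
  }
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  if (is.null(at$alt)) at$alt <- ""
  at$alt[is.na(at$alt)] <- ""
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  ukey <- unique(key)
  R <- length(ukey)
  tmpl <- residue_templates()
  aa <- character(R); chain <- character(R); resno <- integer(R)
  insert <- character(R)
  atom14 <- array(NA_real_, c(R, 14, 3))
  mask <- matrix(FALSE, R, 14)
  rows_of <- split(seq_len(nrow(at)), factor(key, levels = ukey))
  for (r in seq_len(R)) {
    rows <- rows_of[[r]]
    first <- rows[1]
    resid <- at$resid[first]
    aa[r] <- if (resid %in% AA3) resid else "UNK"
    chain[r] <- at$chain[first]
    resno[r] <- at$resno[first]
    insert[r] <- at$insert[first]
    tp <- tmpl[[aa[r]]]
    names14 <- if (is.null(tp)) c("N", "CA", "C", "O") else tp$atom_names
    # altloc conflicts: highest occupancy wins, then label (file) order
    rows <- rows[order(-at$o[rows], seq_along(rows))]
    for (rr in rows) {
      slot <- match(at$elety[rr], names14)
      if (is.na(slot) || mask[r, slot]) next
      atom14[r, slot, ] <- c(at$x[rr], at$y[rr], at$z[rr])
      mask[r, slot] <- TRUE
    }
  }
  out <- chi_structure(aa, atom14, mask, chain = chain, resno = resno)
  attr(out, "insert") <- insert
  out
}

#' Write a structure to PDB or mmCIF
#'
#' @param record a [chi_structure()].
#' @param path output file.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (extension-based; structures
#'   with more than 62 chains are written as mmCIF regardless, with a
#'   warning).
#' @param bfactor optional per-residue scalar written into the B-factor
#'   column of every atom of the residue (e.g. predicted RMSD).
#' @return the path written, invisibly.
#' @export
write_structure <- function(record, path, format = c("auto", "pdb", "cif"),
                            bfactor = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  n_chain <- length(unique(record$chain))
  if (format == "pdb" && n_chain > 62) {
    warning("more than 62 chains cannot be expressed in PDB; writing mmCIF")
    format <- "cif"
    path <- sub("\\.pdb$", ".cif", path, ignore.case = TRUE)
  }
  tmpl <- residue_templates()
  R <- n_residues(record)
  rows <- list()
  for (i in seq_len(R)) {
    tp <- tmpl[[record$aa[i]]]
    names14 <- if (is.null(tp)) c("N", "CA", "C", "O") else tp$atom_names
    elem14 <- if (is.null(tp)) c("N", "C", "C", "O") else tp$elements
    for (s in which(record$atom_mask[i, ])) {
      if (!all(is.finite(record$atom14[i, s, ]))) next
      rows[[length(rows) + 1]] <- data.frame(
        res = i, elety = names14[s], elem = elem14[s],
        x = record$atom14[i, s, 1], y = record$atom14[i, s, 2],
        z = record$atom14[i, s, 3])
    }
  }
  df <- do.call(rbind, rows)
  b <- if (is.null(bfactor)) rep(0, nrow(df)) else bfactor[df$res]
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(df[, c("x", "y", "z")]))),
                     resno = record$resno[df$res],
                     resid = record$aa[df$res],
                     chain = record$chain[df$res],
                     elety = df$elety,
                     eleno = seq_len(nrow(df)),
                     o = rep(1, nrow(df)), b = b)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_chiflow", "#", "loop_",
                 "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.type_symbol", "_atom_site.label_atom_id",
                 "_atom_site.label_alt_id", "_atom_site.label_comp_id",
                 "_atom_site.label_asym_id", "_atom_site.label_entity_id",
                 "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
                 "_atom_site.Cartn_x", "_atom_site.Cartn_y",
                 "_atom_site.Cartn_z", "_atom_site.occupancy",
                 "_atom_site.B_iso_or_equiv",
                 "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
                 "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
                 "_atom_site.auth_atom_id",
                 "_atom_site.pdbx_PDB_model_num"), con)
    writeLines(sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
      seq_len(nrow(df)), df$elem, df$elety, record$aa[df$res],
      record$chain[df$res], record$resno[df$res], df$x, df$y, df$z, b,
      record$resno[df$res], record$aa[df$res], record$chain[df$res],
      df$elety), con)
    writeLines("#", con)
  }
  invisible(path)
}

#' Apply the dataset curation filters
#'
#' Removes residues missing any of N/CA/C, removes the later residue of any
#' C-alpha pair closer than the tolerance, then rejects structures shorter
#' than the minimum length or with too many unknown residues. Filtering is
#' idempotent. Rejection is a value, not an error.
#'
#' @param record a [chi_structure()].
#' @param config a [filter_config()].
#' @return list with `accepted` (logical), `record` (the filtered
#'   [chi_structure()], or `NULL` when rejected), and `reason` (`NA` or a
#'   short string).
#' @export
apply_filters <- function(record, config = filter_config()) {
  R <- n_residues(record)
  has_bb <- apply(record$atom_mask[, 1:3, drop = FALSE], 1, all) &
    apply(is.finite(record$atom14[, 1:3, , drop = FALSE]), 1, all)
  keep <- which(has_bb)
  if (length(keep) >= 2) {
    ca <- record$atom14[keep, 2, , drop = TRUE]
    d <- as.matrix(stats::dist(ca))
    drop <- rep(FALSE, length(keep))
    for (a in seq_along(keep)) {
      if (drop[a]) next
      close_later <- which(d[a, ] < config$ca_clash_tolerance)
      close_later <- close_later[close_later > a]
      drop[close_later] <- TRUE
    }
    keep <- keep[!drop]
  }
  if (!length(keep)) {
    return(list(accepted = FALSE, record = NULL, reason = "no valid residues"))
  }
  rec <- subset_structure(record, keep)
  if (n_residues(rec) < config$min_residues) {
    return(list(accepted = FALSE, record = NULL,
                reason = sprintf("fewer than %d residues",
                                 config$min_residues)))
  }
  if (mean(rec$aa == "UNK") > config$max_unknown_fraction) {
    return(list(accepted = FALSE, record = NULL,
                reason = sprintf("more than %.0f%% unknown residues",
                                 100 * config$max_unknown_fraction)))
  }
  list(accepted = TRUE, record = rec, reason = NA_character_)
}
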