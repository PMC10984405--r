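#' Read a PDB file into an atomic model
#'
#' ATOM/HETATM records are parsed with bio3d; CONECT records are read
#' directly so glycosidic and other explicit bonds survive the round trip.
#' Coordinates are converted from Angstrom to nm. Glycan residues are
#' flagged by the PDB chemical-component glycan set
#' (see [is_glycan_residue()]); hydrogens bonded (via CONECT) to N, O or S
#' are flagged exchangeable.
#'
#' @param path Path to a PDB file.
#' @param glycan_residues Extra residue names to treat as glycans.
#' @return An [atomic_model()].
#' @export
read_pdb <- function(path, glycan_residues = character()) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("Failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  if (nrow(at) == 0) abort(paste("No ATOM/HETATM records in", path))
  elesy <- trimws(at$elesy)
  # infer missing element symbols from the atom name (first letter run)
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) {
    guess <- sub("^[0-9']*", "", trimws(at$elety[blank]))
    elesy[blank] <- substr(guess, 1, 1)
  }
  bad <- !(.element_key(elesy) %in% names(.element_xray_b))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Unknown element '%s' at atom %d (%s %s %s); known elements: %s",
      elesy[i], at$eleno[i], at$elety[i], at$resid[i], at$resno[i],
      paste(sub("_$", "", names(.element_xray_b)), collapse = " ")))
  }
  seg <- trimws(at$segid)
  seg[is.na(seg) | seg == ""] <- trimws(at$chain[is.na(seg) | seg == ""])
  seg[is.na(seg) | seg == ""] <- "A"
  atoms <- tibble(
    element = elesy,
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    segment_id = seg,
    x = at$x / 10, y = at$y / 10, z = at$z / 10
  )
  bonds <- .read_conect(path, at$eleno)
  model <- atomic_model(atoms, bonds = bonds,
                        glycan_residues = glycan_residues)
  model$atoms$is_exchangeable <- .flag_exchangeable(model)
  model
}

# CONECT records: columns 7-11, 12-16, ... are 5-wide serial fields
.read_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0) return(NULL)
  idx <- setNames(seq_along(serials), as.character(serials))
  out <- list()
  for (ln in lines) {
    fields <- c()
    for (start in seq(7, nchar(ln) - 1, by = 5)) {
      f <- trimws(substr(ln, start, start + 4))
      if (nzchar(f)) fields <- c(fields, f)
    }
    if (length(fields) < 2) next
    a <- idx[fields[1]]
    bs <- idx[fields[-1]]
    ok <- !is.na(a) & !is.na(bs)
    if (any(ok)) out[[length(out) + 1]] <- cbind(a, bs[ok])
  }
  if (length(out) == 0) return(NULL)
  b <- do.call(rbind, out)
  b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  unique(b)
}

.flag_exchangeable <- function(model) {
  a <- model$atoms
  exch <- rep(FALSE, nrow(a))
  if (nrow(model$bonds) == 0 || !any(a$is_hydrogen)) return(exch)
  polar <- .element_key(a$element) %in% c("N", "O", "S")
  b <- model$bonds
  h1 <- a$is_hydrogen[b[, 1]] & polar[b[, 2]]
  h2 <- a$is_hydrogen[b[, 2]] & polar[b[, 1]]
  exch[b[h1, 1]] <- TRUE
  exch[b[h2, 2]] <- TRUE
  exch
}

#' Write an atomic model to a PDB file
#'
#' Glycan atoms are written as HETATM records; all stored bonds (including
#' glycosidic bonds created by [attach_glycan()]) are written as CONECT
#' records. Coordinates are converted nm -> Angstrom at the standard PDB
#' precision of 0.001 Angstrom (0.0001 nm).
#'
#' @param model An [atomic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  if (!inherits(model, "atomic_model") || n_atoms(model) == 0) {
    abort("Refusing to write an empty or invalid model")
  }
  a <- model$atoms
  xyz <- as.vector(t(coords(model) * 10))
  chain <- substr(a$segment_id, 1, 1)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path, xyz = xyz,
      type = ifelse(a$is_glycan, "HETATM", "ATOM"),
      resno = a$residue_number, resid = a$residue_name,
      eleno = seq_len(nrow(a)), elety = a$atom_name,
      chain = chain, segid = a$segment_id, elesy = a$element,
      o = rep(1, nrow(a)), b = rep(0, nrow(a)),
      print.segid = TRUE, end = FALSE)
    TRUE
  }, error = function(e) abort(paste0("Cannot write '", path, "': ",
                                      conditionMessage(e))))
  con <- file(path, "a")
  on.exit(close(con))
  if (nrow(model$bonds) > 0) {
    b <- model$bonds
    writeLines(sprintf("CONECT%5d%5d", b[, 1], b[, 2]), con)
  }
  writeLines("END", con)
  invisible(path)
}
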