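#' Protein structure container
#'
#' A `pdb_structure` is a light container around an atom table in author
#' (PDB) residue numbering: one row per atom with chain, residue number,
#' residue name, atom name, element, Cartesian coordinates (Angstrom) and a
#' HETATM flag. Residues are kept ordered by residue number within each
#' chain. An optional secondary-structure annotation (see [ss_map()]) and a
#' model id travel with the object.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `elety`
#'   (atom name), `elesy` (element symbol), `x`, `y`, `z`, `het` (logical)
#' @param model_id integer model number
#' @param annotation optional secondary-structure map from [ss_map()]
#' @return object of class `pdb_structure`
#' @export
pdb_structure <- function(atoms, model_id = 1L, annotation = NULL) {
  need <- c("chain", "resno", "resname", "elety", "elesy", "x", "y", "z", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty atom table")
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$elety))) stop("empty atom name")
  # at most one atom per name per residue
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$het)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue: ", key[anyDuplicated(key)])
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 annotation = annotation),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms[!x$atoms$het, , drop = FALSE]
  nres <- length(unique(paste(a$chain, a$resno)))
  cat(sprintf("<pdb_structure> model %d: %d residues, %d atoms (%d HETATM)\n",
              x$model_id, nres, nrow(x$atoms), sum(x$atoms$het)))
  if (!is.null(x$annotation))
    cat(sprintf("  annotation: %d secondary-structure elements\n",
                nrow(x$annotation)))
  invisible(x)
}

#' Number of (polymer) residues
#' @param s a `pdb_structure`
#' @param het include HETATM residues in the count
#' @export
n_residues <- function(s, het = FALSE) {
  a <- s$atoms
  if (!het) a <- a[!a$het, , drop = FALSE]
  length(unique(paste(a$chain, a$resno)))
}

is_pdb_record <- function(x) {
  grepl("^(ATOM|HETATM|MODEL|ENDMDL|CONECT|HEADER|TITLE|REMARK|TER|END)", x)
}

parse_pdb_lines <- function(lines, model = 1L, keep_het = FALSE) {
  trim <- function(x) gsub("^\\s+|\\s+$", "", x)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | (keep_het & rec == "HETATM") |
    (!keep_het & FALSE)
  is_any_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- trim(rec) == "MODEL"
  # assign model index to every line
  model_idx <- cumsum(is_model)
  if (!any(is_model)) model_idx <- rep(1L, length(lines)) else
    model_idx[model_idx == 0L] <- 1L
  n_models <- max(model_idx[is_any_atom], 1L)
  if (model > n_models)
    stop(sprintf("model %d not found (file has %d model(s))", model, n_models))
  keep <- is_any_atom & model_idx == model
  if (keep_het) sel <- keep else sel <- keep & rec == "ATOM  "
  if (!any(is_any_atom)) stop("no ATOM/HETATM records in input")
  if (!any(sel)) stop(sprintf("no ATOM records in model %d", model))
  ln <- which(sel)
  txt <- lines[sel]
  bad <- nchar(txt) < 54
  if (any(bad))
    stop(sprintf("malformed ATOM line %d: fewer than 54 columns", ln[which(bad)[1]]))
  icode <- trim(substr(txt, 27, 27))
  if (any(nzchar(icode)))
    stop(sprintf("insertion codes are not supported (line %d)",
                 ln[which(nzchar(icode))[1]]))
  xyz <- suppressWarnings(cbind(as.numeric(substr(txt, 31, 38)),
                                as.numeric(substr(txt, 39, 46)),
                                as.numeric(substr(txt, 47, 54))))
  if (any(!is.finite(xyz))) {
    bad1 <- which(!is.finite(rowSums(xyz)))[1]
    stop(sprintf("malformed ATOM line %d: unreadable coordinates", ln[bad1]))
  }
  resno <- suppressWarnings(as.integer(substr(txt, 23, 26)))
  if (any(is.na(resno)))
    stop(sprintf("malformed ATOM line %d: unreadable residue number",
                 ln[which(is.na(resno))[1]]))
  alt <- trim(substr(txt, 17, 17))
  df <- data.frame(chain = substr(txt, 22, 22),
                   resno = resno,
                   resname = trim(substr(txt, 18, 20)),
                   elety = trim(substr(txt, 13, 16)),
                   elesy = trim(substr(txt, 77, 78)),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   het = substr(txt, 1, 6) == "HETATM",
                   stringsAsFactors = FALSE)
  # keep first altloc only
  df <- df[alt == "" | alt == "A", , drop = FALSE]
  df$elesy[!nzchar(df$elesy)] <- substr(df$elety[!nzchar(df$elesy)], 1, 1)
  df
}

#' Read a structure from PDB-format text
#'
#' Parses fixed-width ATOM/HETATM records of one model. Alternate location
#' 'A' is kept when altlocs are present; insertion codes are rejected.
#'
#' @param x path to a PDB file, or a character vector of PDB lines (a single
#'   string containing newlines is also accepted)
#' @param model 1-based model index (default first model)
#' @param keep_het keep HETATM records (heme, waters, ions); default FALSE
#' @return a [pdb_structure()]
#' @export
read_structure <- function(x, model = 1L, keep_het = FALSE) {
  if (length(x) == 1L && !grepl("\n", x) && !is_pdb_record(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  pdb_structure(parse_pdb_lines(lines, model = model, keep_het = keep_het),
                model_id = model)
}

#' Read every model of a multi-model PDB file
#' @inheritParams read_structure
#' @return list of [pdb_structure()], one per model
#' @export
read_models <- function(x, keep_het = FALSE) {
  if (length(x) == 1L && !grepl("\n", x) && !is_pdb_record(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    lines <- readLines(x, warn = FALSE)
  } else lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  n <- max(1L, sum(gsub("\\s+$", "", substr(lines, 1, 6)) == "MODEL"))
  lapply(seq_len(n), function(i)
    pdb_structure(parse_pdb_lines(lines, model = i, keep_het = keep_het),
                  model_id = i))
}

format_atom_lines <- function(a, serial0 = 0L) {
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinate magnitude >= 10000 A cannot be written in PDB fixed width")
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  nm <- a$elety
  # PDB atom-name justification: 1-char element names start in column 14
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial0 + seq_len(nrow(a)), nm4, a$resname, a$chain, a$resno,
          a$x, a$y, a$z, 1, 0, a$elesy)
}

#' Write one structure (or a list of structures) as PDB text
#'
#' A list input is written as a multi-model file with MODEL/ENDMDL blocks.
#' Coordinates use the fixed-width 8.3 PDB convention, so round-tripping
#' preserves them to 0.001 Angstrom.
#'
#' @param s a [pdb_structure()] or a list of them
#' @param file optional path; when NULL the text is returned invisibly only
#' @return character vector of PDB lines (invisibly when `file` is given)
#' @export
write_structure <- function(s, file = NULL) {
  if (inherits(s, "pdb_structure")) {
    lines <- c(format_atom_lines(s$atoms), "TER", "END")
  } else if (is.list(s) && length(s) && all(vapply(s, inherits, TRUE, "pdb_structure"))) {
    lines <- unlist(lapply(seq_along(s), function(i)
      c(sprintf("MODEL     %4d", i), format_atom_lines(s[[i]]$atoms),
        "TER", "ENDMDL")), use.names = FALSE)
    lines <- c(lines, "END")
  } else stop("s must be a pdb_structure or a non-empty list of them")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Extract amide N-H unit bond vectors
#'
#' Returns one unit vector per residue possessing both a backbone N and an
#' amide hydrogen (atom name "H" preferred, "HN" accepted). Prolines and
#' residues lacking the hydrogen are skipped; the numbers skipped are
#' attached as the `"report"` attribute.
#'
#' @param s a [pdb_structure()]
#' @return data.frame (class `bond_vectors`) with columns `resno`, `ux`,
#'   `uy`, `uz`
#' @export
nh_vectors <- function(s) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  res <- unique(a[, c("chain", "resno", "resname")])
  out <- vector("list", nrow(res))
  n_pro <- 0L; n_noh <- 0L
  for (i in seq_len(nrow(res))) {
    ri <- a[a$chain == res$chain[i] & a$resno == res$resno[i], , drop = FALSE]
    if (res$resname[i] == "PRO") { n_pro <- n_pro + 1L; next }
    N <- ri[ri$elety == "N", , drop = FALSE]
    H <- ri[ri$elety == "H", , drop = FALSE]
    if (nrow(H) == 0L) H <- ri[ri$elety == "HN", , drop = FALSE]
    if (nrow(N) != 1L || nrow(H) != 1L) { n_noh <- n_noh + 1L; next }
    v <- c(H$x - N$x, H$y - N$y, H$z - N$z)
    u <- unitize(v)
    out[[i]] <- data.frame(resno = res$resno[i], ux = u[1], uy = u[2], uz = u[3])
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stop("no N-H bond vectors could be extracted")
  rownames(out) <- NULL
  attr(out, "report") <- c(n_proline = n_pro, n_missing_h = n_noh)
  class(out) <- c("bond_vectors", "data.frame")
  out
}

#' Shift author residue numbering by a constant offset
#'
#' Applies the offset to every residue number and to the annotation ranges,
#' e.g. +4 maps a solution-structure numbering onto a crystal-structure
#' numbering that includes four extra N-terminal residues.
#'
#' @param s a [pdb_structure()]
#' @param offset integer added to every residue number
#' @export
apply_numbering_offset <- function(s, offset) {
  offset <- as.integer(offset)
  s$atoms$resno <- s$atoms$resno + offset
  if (!is.null(s$annotation)) {
    s$annotation$start <- s$annotation$start + offset
    s$annotation$end <- s$annotation$end + offset
  }
  s
}

#' Secondary-structure annotation map
#'
#' Annotation is supplied, not computed: element label, author-numbering
#' start/end and kind ("helix" or "strand"), mirroring the standard P450
#' element naming (A-L helices, beta1-beta5 strands).
#'
#' @param label character element labels (unique)
#' @param start,end integer author residue numbers, start <= end
#' @param kind "helix" or "strand"
#' @return data.frame of class `ss_map`
#' @export
ss_map <- function(label, start, end, kind) {
  kind <- match.arg(kind, c("helix", "strand"), several.ok = TRUE)
  if (length(kind) == 1L) kind <- rep(kind, length(label))
  if (any(start > end)) stop("ss_map: start > end")
  if (anyDuplicated(label)) stop("ss_map: duplicate labels")
  df <- data.frame(label = label, start = as.integer(start),
                   end = as.integer(end), kind = kind,
                   stringsAsFactors = FALSE)
  for (k in unique(df$kind)) {
    dk <- df[df$kind == k, , drop = FALSE]
    if (nrow(dk) > 1L) {
      dk <- dk[order(dk$start), , drop = FALSE]
      if (any(dk$start[-1] <= dk$end[-nrow(dk)]))
        stop("ss_map: overlapping ranges within kind ", k)
    }
  }
  class(df) <- c("ss_map", "data.frame")
  df
}

#' Residue numbers covered by named annotation elements
#' @param map an [ss_map()]
#' @param labels element labels; default all
#' @return sorted integer vector of author residue numbers
#' @export
ss_residues <- function(map, labels = map$label) {
  m <- map[map$label %in% labels, , drop = FALSE]
  if (nrow(m) == 0L) stop("no annotation elements match: ",
                          paste(labels, collapse = ", "))
  sort(unique(unlist(mapply(seq, m$start, m$end, SIMPLIFY = FALSE))))
}

#' Coordinates of one named atom per residue
#'
#' @param s a [pdb_structure()]
#' @param resnos residue numbers (author numbering); default all
#' @param elety atom name, default "CA"
#' @return matrix with one row per found residue, rownames = residue number
#' @export
atom_coords <- function(s, resnos = NULL, elety = "CA") {
  a <- s$atoms[!s$atoms$het & s$atoms$elety == elety, , drop = FALSE]
  if (!is.null(resnos)) a <- a[a$resno %in% resnos, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' One-letter amino-acid sequence of a structure
#' @param s a [pdb_structure()]
#' @return single character string
#' @export
structure_sequence <- function(s) {
  a <- s$atoms[!s$atoms$het & s$atoms$elety == "CA", , drop = FALSE]
  paste(bio3d::aa321(a$resname), collapse = "")
}
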