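# Multi-chain structure container and PDB I/O.
#
# A complex is stored as a flat atom table (one row per atom) plus a subunit
# table, much like the atom record data.frame used by bio3d.  All coordinates
# are in Angstrom, author residue numbering is kept as-is.

#' Van der Waals radii used throughout the package
#'
#' Standard heavy-atom radii (Angstrom). Elements not listed fall back to the
#' carbon radius.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2)
}

.element_radius <- function(elesy, table = vdw_radii()) {
  r <- unname(table[elesy])
  r[is.na(r)] <- table[["C"]]
  r
}

.element_number <- function(elesy) {
  z <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15)
  out <- unname(z[elesy])
  out[is.na(out)] <- 6
  out
}

# infer the element symbol from a PDB atom name ("NZ" -> "N", "1HB" -> "H")
.infer_element <- function(elety) {
  e <- gsub("[0-9' ]", "", elety)
  toupper(substr(e, 1, 1))
}

#' Construct a protein-complex object from an atom table
#'
#' Low-level constructor used by the PDB reader and the synthetic fixture
#' generators. One subunit per chain; the `entity` column groups chains with
#' identical residue-type sequences (copies in a homo-oligomer) and
#' `copy_index` numbers the copies within each entity.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter residue type), `elety` (atom name), `x`, `y`, `z` and
#'   optionally `elesy` (element symbol, inferred from `elety` if absent).
#' @param name label for the complex.
#' @return An object of class `xl_complex`.
#' @export
xl_complex <- function(atoms, name = "complex") {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("atom table is empty")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("all atom coordinates must be finite")
  if (is.null(atoms$elesy)) atoms$elesy <- .infer_element(atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  chains <- unique(atoms$chain)
  if (length(chains) < 2)
    stop("a complex needs at least 2 subunits (chains); got ",
         length(chains))
  # order atoms within chains by author numbering + insertion code
  ord <- order(match(atoms$chain, chains), atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  # entity grouping: identical residue-type sequences are copies
  seqs <- vapply(chains, function(ch) {
    a <- atoms[atoms$chain == ch, ]
    key <- !duplicated(paste(a$resno, a$insert))
    paste(a$resid[key], collapse = "-")
  }, character(1))
  entity <- match(seqs, unique(seqs))
  copy_index <- stats::ave(entity, entity, FUN = seq_along)
  subunits <- data.frame(chain_id = chains, entity = entity,
                         copy_index = copy_index,
                         stringsAsFactors = FALSE)
  structure(list(name = name, atoms = atoms, subunits = subunits),
            class = "xl_complex")
}

#' Read a protein complex from a PDB file
#'
#' Parses ATOM records via bio3d, drops HETATM records, waters and hydrogens,
#' and resolves alternate locations to the highest-occupancy conformer (first
#' on ties). Each chain becomes one subunit.
#'
#' @param file path to a PDB file.
#' @param name label; defaults to the file name.
#' @return An `xl_complex`.
#' @export
read_complex <- function(file, name = NULL) {
  if (is.null(name)) name <- sub("\\.pdb$", "", basename(file))
  pdb <- tryCatch(bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", file, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(a)) stop("no ATOM records after filtering in '", file, "'")
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == ""))
    elesy <- .infer_element(a$elety)
  elesy[is.na(elesy) | elesy == ""] <- .infer_element(a$elety)[
    is.na(elesy) | elesy == ""]
  a$elesy <- toupper(elesy)
  a <- a[a$elesy != "H", , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc: keep highest occupancy per (chain, resno, insert, elety),
  # first record on ties
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(a)), key)[unique(key)],
                        function(i) i[which.max(a$o[i])]),
                 use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]
  ca_per_chain <- tapply(a$elety == "CA", a$chain, sum)
  if (sum(ca_per_chain >= 1) < 2)
    stop("structure must contain at least 2 chains with at least one ",
         "CA atom each")
  xl_complex(a[, c("chain", "resno", "insert", "resid", "elety",
                   "elesy", "x", "y", "z")], name = name)
}

#' Write a complex to a PDB file
#'
#' @param x an `xl_complex`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_complex <- function(x, file) {
  stopifnot(inherits(x, "xl_complex"))
  a <- x$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   elesy = a$elesy, o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(file)
}

#' @export
print.xl_complex <- function(x, ...) {
  cat("Protein complex '", x$name, "': ", nrow(x$subunits),
      " subunits, ", nrow(x$atoms), " atoms\n", sep = "")
  rt <- residue_table(x)
  for (i in seq_len(nrow(x$subunits))) {
    ch <- x$subunits$chain_id[i]
    cat("  chain ", ch, ": ", sum(rt$chain == ch), " residues (entity ",
        x$subunits$entity[i], ", copy ", x$subunits$copy_index[i], ")\n",
        sep = "")
  }
  invisible(x)
}

#' Residue-level view of a complex
#'
#' One row per residue, with the designated anchor atom used as the residue
#' position for all distance computations: lysine NZ when present, otherwise
#' CB, otherwise CA (the chemically reactive amine, with fallbacks for
#' truncated side chains).
#'
#' @param x an `xl_complex`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `anchor` (atom name), `ax`, `ay`, `az` (anchor coordinates) and
#'   `aelesy` (anchor element).
#' @export
residue_table <- function(x) {
  stopifnot(inherits(x, "xl_complex"))
  a <- x$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(a)), key)[unique(key)]
  pick <- vapply(idx, function(i) {
    nm <- a$elety[i]
    j <- match("NZ", nm)
    if (is.na(j)) j <- match("CB", nm)
    if (is.na(j)) j <- match("CA", nm)
    if (is.na(j)) j <- 1L
    i[j]
  }, integer(1))
  out$anchor <- a$elety[pick]
  out$ax <- a$x[pick]
  out$ay <- a$y[pick]
  out$az <- a$z[pick]
  out$aelesy <- a$elesy[pick]
  rownames(out) <- NULL
  out
}

# locate rows of residue_table for (chain, resno) pairs; NA when absent
.match_residues <- function(rt, chain, resno) {
  match(paste(chain, resno, sep = "\r"),
        paste(rt$chain, rt$resno, sep = "\r"))
}

#' Crosslinkable residues of a complex
#'
#' @param x an `xl_complex`.
#' @param residue_types 3-letter codes treated as crosslinkable
#'   (default lysine only; the supported crosslinkers are amine-reactive).
#' @return subset of [residue_table()] rows.
#' @export
crosslinkable_residues <- function(x, residue_types = "LYS") {
  rt <- residue_table(x)
  rt[rt$resid %in% residue_types, , drop = FALSE]
}

# coordinates of all atoms of one chain as a matrix
.chain_coords <- function(x, chain, elety = NULL) {
  a <- x$atoms[x$atoms$chain == chain, , drop = FALSE]
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# apply a rigid transform (3x3 rotation + translation) to selected chains
.transform_chains <- function(x, chains, rot = diag(3), trans = c(0, 0, 0),
                              center = NULL) {
  sel <- x$atoms$chain %in% chains
  m <- as.matrix(x$atoms[sel, c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(m)
  m <- sweep(m, 2, center) %*% t(rot)
  m <- sweep(m, 2, center + trans, FUN = "+")
  x$atoms[sel, c("x", "y", "z")] <- m
  x
}
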