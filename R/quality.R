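# Ground-truth model accuracy against a native structure: per-subunit mean
# C-alpha RMSD and the fraction of native inter-subunit contacts (fnat).

# matched CA coordinate matrices (model, native) keyed by chain+resno+insert
.matched_ca <- function(model, native) {
  ca_m <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  ca_n <- native$atoms[native$atoms$elety == "CA", , drop = FALSE]
  key_m <- paste(ca_m$chain, ca_m$resno, ca_m$insert, sep = "\r")
  key_n <- paste(ca_n$chain, ca_n$resno, ca_n$insert, sep = "\r")
  chains <- unique(ca_n$chain)
  for (ch in chains) {
    nm <- sum(ca_m$chain == ch); nn <- sum(ca_n$chain == ch)
    if (nm != nn)
      stop("CA count mismatch for subunit ", ch, ": model ", nm,
           ", native ", nn)
  }
  idx <- match(key_n, key_m)
  if (anyNA(idx)) stop("model and native residues do not correspond")
  list(model = as.matrix(ca_m[idx, c("x", "y", "z")]),
       native = as.matrix(ca_n[, c("x", "y", "z")]),
       chain = ca_n$chain)
}

#' Mean per-subunit C-alpha RMSD of a model against the native
#'
#' For each subunit in turn, the whole model is least-squares superposed
#' onto the native using only that subunit's CA atoms, and the whole-model
#' CA RMSD is computed; the mean over subunits is returned.
#'
#' @param model,native `xl_complex` objects with corresponding subunits and
#'   equal CA counts per subunit.
#' @return mean RMSD in Angstrom.
#' @export
mean_rmsd <- function(model, native) {
  m <- .matched_ca(model, native)
  chains <- unique(m$chain)
  fixed <- as.numeric(t(m$native))
  mobile <- as.numeric(t(m$model))
  rmsds <- vapply(chains, function(ch) {
    sel <- which(m$chain == ch)
    inds <- bio3d::atom2xyz(sel)
    moved <- bio3d::fit.xyz(fixed, mobile, fixed.inds = inds,
                            mobile.inds = inds)
    dif <- matrix(moved - fixed, ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums(dif^2)))
  }, numeric(1))
  mean(rmsds)
}

# inter-subunit residue contact pairs (any-atom distance <= cutoff);
# returns a character vector of pair keys
.contact_pairs <- function(x, cutoff = 5) {
  a <- x$atoms
  chains <- unique(a$chain)
  keys <- character(0)
  for (i in seq_along(chains)) {
    ai <- a[a$chain == chains[i], , drop = FALSE]
    mi <- as.matrix(ai[, c("x", "y", "z")])
    for (j in seq_along(chains)) {
      if (j <= i) next
      aj <- a[a$chain == chains[j], , drop = FALSE]
      mj <- as.matrix(aj[, c("x", "y", "z")])
      d2 <- outer(rowSums(mi^2), rowSums(mj^2), "+") -
        2 * tcrossprod(mi, mj)
      hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
      if (!nrow(hit)) next
      keys <- c(keys, unique(paste(
        chains[i], ai$resno[hit[, 1]], ai$insert[hit[, 1]],
        chains[j], aj$resno[hit[, 2]], aj$insert[hit[, 2]], sep = "\r")))
    }
  }
  unique(keys)
}

#' Fraction of native inter-subunit contacts preserved in a model (fnat)
#'
#' Native interface pairs are inter-subunit residue pairs with any-atom
#' distance within `cutoff` (5 A, inclusive) in the native; the returned
#' fraction is the proportion of those pairs also in contact in the model.
#'
#' @param model,native `xl_complex` objects with corresponding subunits.
#' @param cutoff contact distance, Angstrom.
#' @return fraction in `[0, 1]`; errors (condition class
#'   `xlscore_no_interface`) when the native has no interface pairs.
#' @export
fnat <- function(model, native, cutoff = 5) {
  native_pairs <- .contact_pairs(native, cutoff)
  if (!length(native_pairs))
    stop(structure(class = c("xlscore_no_interface", "error",
                             "condition"),
                   list(message = "native structure has no inter-subunit contacts; fnat undefined",
                        call = sys.call())))
  model_pairs <- .contact_pairs(model, cutoff)
  mean(native_pairs %in% model_pairs)
}

#' Model quality metrics and the positive-model criterion
#'
#' A model is positive (acceptable) when its mean per-subunit RMSD is at
#' most 4 A and its fnat at least 0.3 (matching the medium-accuracy CAPRI
#' criterion). When fnat is undefined the model is never positive.
#'
#' @param model,native `xl_complex` objects.
#' @param rmsd_max,fnat_min thresholds of the positive criterion.
#' @return one-row data.frame: `mean_rmsd`, `fnat`, `positive`.
#' @export
model_quality <- function(model, native, rmsd_max = 4, fnat_min = 0.3) {
  mr <- mean_rmsd(model, native)
  fn <- tryCatch(fnat(model, native),
                 xlscore_no_interface = function(e) NA_real_)
  data.frame(mean_rmsd = mr, fnat = fn,
             positive = !is.na(fn) && mr <= rmsd_max && fn >= fnat_min)
}
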