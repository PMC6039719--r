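# Crosslink restraint table and tabular I/O.
#
# A crosslink set is a data.frame with one row per restraint:
#   chain_a res_a chain_b res_b linker classification
# classification is "inter", "intra" or "unresolved" (homo-complex rows whose
# chain assignment is ambiguous, marked with "?" in the input table).

#' Default crosslinker geometry
#'
#' BS3/DSS-style amine-reactive crosslinker: 11.4 A linker arm, maximum
#' solvent-accessible surface distance 32 A, maximum Euclidean distance 30 A.
#'
#' @return list with `linker_arm`, `max_bound_sasd`, `max_bound_ed`.
#' @export
default_linker <- function() {
  list(linker_arm = 11.4, max_bound_sasd = 32, max_bound_ed = 30)
}

.xl_cols <- c("chain_a", "res_a", "chain_b", "res_b", "linker",
              "classification")

.as_crosslinks <- function(df) {
  df <- df[, .xl_cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("xl_links", "data.frame")
  df
}

#' Build a crosslink table from vectors
#'
#' @param chain_a,res_a,chain_b,res_b endpoint chains and author residue
#'   numbers; `"?"` in a chain marks homo-complex ambiguity.
#' @param linker linker arm length in Angstrom.
#' @param complex optional `xl_complex` used to classify rows.
#' @return crosslink data.frame (class `xl_links`).
#' @export
crosslinks <- function(chain_a, res_a, chain_b, res_b,
                       linker = default_linker()$linker_arm,
                       complex = NULL) {
  df <- data.frame(chain_a = as.character(chain_a),
                   res_a = as.integer(res_a),
                   chain_b = as.character(chain_b),
                   res_b = as.integer(res_b),
                   linker = rep_len(as.numeric(linker),
                                    length(chain_a)),
                   stringsAsFactors = FALSE)
  if (any(df$linker <= 0)) stop("linker arm must be strictly positive")
  same <- df$chain_a == df$chain_b & df$res_a == df$res_b
  if (any(same & df$chain_a != "?"))
    stop("a crosslink must join two distinct residues")
  df$classification <- ifelse(df$chain_a == "?" | df$chain_b == "?",
                              "unresolved",
                              ifelse(df$chain_a == df$chain_b,
                                     "intra", "inter"))
  .as_crosslinks(df)
}

#' Read a crosslink table
#'
#' Tab-separated text with header `chain_a res_a chain_b res_b [linker]`;
#' lines starting with `#` are comments; `"?"` in a chain column marks a
#' homo-complex row with ambiguous chain assignment. Rows referencing
#' residues absent from `complex` are dropped with a warning; the exclusion
#' report is attached as attribute `"report"`.
#'
#' @param file path to the table.
#' @param complex `xl_complex` the restraints refer to.
#' @return crosslink data.frame (class `xl_links`).
#' @export
read_crosslinks <- function(file, complex) {
  stopifnot(inherits(complex, "xl_complex"))
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chain_a", "res_a", "chain_b", "res_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("crosslink table is missing columns: ",
         paste(miss, collapse = ", "))
  if (is.null(df$linker) || all(df$linker == ""))
    df$linker <- default_linker()$linker_arm
  xl <- crosslinks(df$chain_a, as.integer(df$res_a),
                   df$chain_b, as.integer(df$res_b),
                   as.numeric(df$linker))
  rt <- residue_table(complex)
  ok_end <- function(chain, resno) {
    amb <- chain == "?"
    found <- !is.na(.match_residues(rt, chain, resno))
    # ambiguous ends must exist in at least one chain
    found[amb] <- resno[amb] %in% rt$resno
    found
  }
  ok <- ok_end(xl$chain_a, xl$res_a) & ok_end(xl$chain_b, xl$res_b)
  report <- data.frame(row = which(!ok),
                       chain_a = xl$chain_a[!ok], res_a = xl$res_a[!ok],
                       chain_b = xl$chain_b[!ok], res_b = xl$res_b[!ok])
  if (any(!ok))
    warning(sum(!ok), " crosslink row(s) reference residues absent from ",
            "the complex and were excluded")
  out <- .as_crosslinks(xl[ok, , drop = FALSE])
  attr(out, "report") <- report
  out
}

#' Write a crosslink table
#'
#' @param xl crosslink data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_crosslinks <- function(xl, file) {
  utils::write.table(xl[, c("chain_a", "res_a", "chain_b", "res_b",
                            "linker")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
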