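# SASD and Euclidean distances between crosslinkable residue pairs.

#' Euclidean distance between residue anchor atoms
#'
#' @param complex an `xl_complex`.
#' @param pairs data.frame with columns `chain_a`, `res_a`, `chain_b`,
#'   `res_b`.
#' @return numeric vector of distances in Angstrom.
#' @export
compute_ed <- function(complex, pairs) {
  rt <- residue_table(complex)
  ia <- .match_residues(rt, pairs$chain_a, pairs$res_a)
  ib <- .match_residues(rt, pairs$chain_b, pairs$res_b)
  if (anyNA(ia) || anyNA(ib))
    stop("pair endpoints not found in the complex")
  sqrt((rt$ax[ia] - rt$ax[ib])^2 + (rt$ay[ia] - rt$ay[ib])^2 +
         (rt$az[ia] - rt$az[ib])^2)
}

#' Solvent-accessible surface distances for residue pairs
#'
#' For each pair, the shortest path through bulk solvent voxels
#' (26-connectivity, Euclidean edge weights) between the solvent voxels
#' adjacent to the two anchor atoms, plus the two anchor-to-entry offsets.
#' Status is `"non_accessible"` when either anchor has no adjacent solvent
#' voxel, `"no_path"` when no route exists within `cap`, otherwise `"ok"`.
#' The Euclidean distance is always reported.
#'
#' One Dijkstra search is run per source endpoint; endpoints are chosen
#' greedily so that each search serves as many pairs as possible.
#'
#' @param complex an `xl_complex`.
#' @param pairs data.frame with columns `chain_a`, `res_a`, `chain_b`,
#'   `res_b`.
#' @param grid optional pre-built `xl_grid` (built on demand otherwise).
#' @param cap path-search bound in Angstrom (> 0).
#' @param ... passed to [build_grid()] when `grid` is `NULL`.
#' @return data.frame: the pair columns plus `status`, `sasd`, `ed`.
#' @export
compute_sasd <- function(complex, pairs, grid = NULL, cap = 60, ...) {
  if (cap <= 0) stop("cap must be strictly positive")
  if (is.null(grid)) grid <- build_grid(complex, ...)
  rt <- residue_table(complex)
  ia <- .match_residues(rt, pairs$chain_a, pairs$res_a)
  ib <- .match_residues(rt, pairs$chain_b, pairs$res_b)
  if (anyNA(ia) || anyNA(ib))
    stop("pair endpoints not found in the complex")
  n <- nrow(pairs)
  out <- pairs[, c("chain_a", "res_a", "chain_b", "res_b"), drop = FALSE]
  out$status <- rep("ok", n)
  out$sasd <- rep(NA_real_, n)
  out$ed <- compute_ed(complex, pairs)

  res_ids <- unique(c(ia, ib))
  entries <- lapply(res_ids, function(i)
    .entry_voxels(grid, c(rt$ax[i], rt$ay[i], rt$az[i]), rt$aelesy[i]))
  names(entries) <- as.character(res_ids)
  acc <- vapply(entries, function(e) length(e$idx) > 0, logical(1))
  acc_of <- function(i) acc[[as.character(i)]]

  bad <- !vapply(ia, acc_of, logical(1)) | !vapply(ib, acc_of, logical(1))
  out$status[bad] <- "non_accessible"
  todo <- which(!bad)
  # greedy source selection: repeatedly run Dijkstra from the endpoint
  # covering the most unresolved pairs
  while (length(todo)) {
    cnt <- table(c(ia[todo], ib[todo]))
    src <- as.integer(names(cnt)[which.max(cnt)])
    e <- entries[[as.character(src)]]
    mine <- todo[ia[todo] == src | ib[todo] == src]
    partners <- setdiff(unique(c(ia[mine], ib[mine])), src)
    tgt <- unlist(lapply(entries[as.character(partners)], `[[`, "idx"),
                  use.names = FALSE)
    dist <- cpp_dijkstra(grid$labels, grid$dim, grid$spacing,
                         as.integer(e$idx - 1L), e$offset, cap,
                         as.integer(tgt - 1L))
    for (p in mine) {
      other <- if (ia[p] == src) ib[p] else ia[p]
      eo <- entries[[as.character(other)]]
      total <- dist[eo$idx] + eo$offset
      best <- suppressWarnings(min(total))
      if (is.finite(best) && best <= cap) {
        out$sasd[p] <- best
      } else {
        out$status[p] <- "no_path"
      }
    }
    todo <- setdiff(todo, mine)
  }
  out
}

#' Enumerate theoretical crosslinks of a complex
#'
#' All unordered pairs of solvent-accessible crosslinkable residues whose
#' SASD is within the crosslinker maximum bound, classified inter/intra.
#'
#' @param complex an `xl_complex`.
#' @param max_bound maximum SASD in Angstrom (default 32, amine-reactive
#'   11.4 A crosslinker).
#' @param residue_types crosslinkable residue types (default lysine).
#' @param grid optional pre-built `xl_grid`.
#' @param cap path-search bound, Angstrom.
#' @param ... passed to [build_grid()].
#' @return crosslink data.frame (class `xl_links`) with extra columns
#'   `sasd` and `ed`.
#' @export
theoretical_crosslinks <- function(complex, max_bound = 32,
                                   residue_types = "LYS", grid = NULL,
                                   cap = 60, ...) {
  if (max_bound <= 0) stop("max_bound must be strictly positive")
  rt <- crosslinkable_residues(complex, residue_types)
  if (nrow(rt) < 2) return(.empty_theoretical())
  comb <- utils::combn(nrow(rt), 2)
  pairs <- data.frame(chain_a = rt$chain[comb[1, ]],
                      res_a = rt$resno[comb[1, ]],
                      chain_b = rt$chain[comb[2, ]],
                      res_b = rt$resno[comb[2, ]],
                      stringsAsFactors = FALSE)
  d <- compute_sasd(complex, pairs, grid = grid,
                    cap = max(cap, max_bound), ...)
  keep <- d$status == "ok" & d$sasd <= max_bound
  if (!any(keep)) return(.empty_theoretical())
  xl <- crosslinks(d$chain_a[keep], d$res_a[keep],
                   d$chain_b[keep], d$res_b[keep])
  xl$sasd <- d$sasd[keep]
  xl$ed <- d$ed[keep]
  xl
}

.empty_theoretical <- function() {
  out <- .as_crosslinks(data.frame(chain_a = character(0),
                                   res_a = integer(0),
                                   chain_b = character(0),
                                   res_b = integer(0),
                                   linker = numeric(0),
                                   classification = character(0)))
  out$sasd <- numeric(0)
  out$ed <- numeric(0)
  out
}

#' Write a batch distance table
#'
#' @param distances output of [compute_sasd()], optionally with a
#'   `classification` column.
#' @param file output path (TSV).
#' @return `file`, invisibly.
#' @export
write_distance_table <- function(distances, file) {
  d <- distances
  if (is.null(d$classification))
    d$classification <- ifelse(d$chain_a == d$chain_b, "intra", "inter")
  utils::write.table(d[, c("chain_a", "res_a", "chain_b", "res_b",
                           "sasd", "ed", "status", "classification")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
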