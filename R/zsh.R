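#' Zero-shot Hamiltonian scan for stabilizing double mutations
#'
#' Runs the full two-stage design pipeline on an alignment of the target
#' protein:
#'
#' 1. *Site discovery* — the alignment is gap-filtered
#'    ([filter_by_gap()]), subsampled to a diverse fixed-size context
#'    ([subsample_diverse()]), and a residue-residue contact map is
#'    estimated by the backend; the `top_pairs` highest-probability position
#'    pairs are selected as candidate sites ([select_top_pairs()]).
#' 2. *Mutation scanning* — at every selected pair all 399 double mutations
#'    are enumerated ([enumerate_double_mutants()]), each mutated sequence
#'    is scored with the Hamiltonian under the backend's likelihood matrix
#'    ([score_variants()]), and the `top_variants` candidates with the
#'    lowest Hamiltonian are reported ([rank_variants()]).
#'
#' With the deterministic baseline backend the whole run is bit-reproducible
#' from its inputs; no random seed is involved.
#'
#' @param x An [msa] of the target protein (query gap-free).
#' @param max_gap_ratio Gap-filter threshold, default `0.15`.
#' @param context_size Diverse-context size, default `64`.
#' @param top_pairs Number of contact pairs to scan, default `1000`.
#' @param top_variants Number of ranked variants to report, default `20`.
#' @param backend Scoring backend, default [baseline_backend()].
#' @return An object of class `zsh`: a list with elements
#'   \describe{
#'     \item{variants}{ranked data frame (`rank`, positions, residues,
#'       `probability`, `hamiltonian`, `delta_vs_wildtype`)}
#'     \item{wt_hamiltonian}{Hamiltonian of the unmutated query}
#'     \item{contact_map}{the stage-one contact map}
#'     \item{pairs}{the selected position pairs}
#'     \item{counts}{sequences kept at each prep step and mutants scored}
#'     \item{config, backend}{the resolved parameters and backend name}
#'   }
#' @examples
#' sim <- simulate_msa(30, 96, data.frame(i = c(4, 12), j = c(20, 27),
#'                     coupling = c(0.9, 0.9)), gap_rate = 0.02, seed = 7)
#' fit <- zsh_scan(sim$msa, top_pairs = 3, top_variants = 5)
#' fit
#' @export
zsh_scan <- function(x, max_gap_ratio = 0.15, context_size = 64L,
                     top_pairs = 1000L, top_variants = 20L,
                     backend = baseline_backend()) {
  stopifnot(inherits(x, "msa"))
  t0 <- proc.time()[["elapsed"]]
  filtered <- filter_by_gap(x, max_gap_ratio)
  context <- subsample_diverse(filtered, context_size)
  cmap <- backend$contact_map(context)
  pairs <- select_top_pairs(cmap, top_pairs)
  query <- query_sequence(context)
  mut_list <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    mm <- enumerate_double_mutants(query, pairs$i[k], pairs$j[k])
    if (!is.null(mm)) {
      mm$probability <- pairs$probability[k]
      mut_list[[k]] <- mm
    }
  }
  mutants <- do.call(rbind, mut_list)
  if (is.null(mutants) || nrow(mutants) == 0L) {
    stop("no scannable pairs (all wild-type residues non-canonical)",
         call. = FALSE)
  }
  scored <- score_variants(query, mutants, context, backend)
  ranked <- rank_variants(scored, top_variants)
  structure(
    list(
      variants = ranked,
      wt_hamiltonian = attr(scored, "wt_hamiltonian"),
      contact_map = cmap,
      pairs = pairs,
      query = query,
      counts = c(input = x$depth, after_gap_filter = filtered$depth,
                 context = context$depth,
                 pairs_scanned = length(Filter(Negate(is.null), mut_list)),
                 mutants_scored = nrow(mutants)),
      config = list(max_gap_ratio = max_gap_ratio,
                    context_size = as.integer(context_size),
                    top_pairs = as.integer(top_pairs),
                    top_variants = as.integer(top_variants)),
      backend = backend$name,
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "zsh"
  )
}

#' @export
print.zsh <- function(x, n = 10L, ...) {
  cat("Zero-shot Hamiltonian double-mutation scan\n")
  cat(sprintf("  context: %d of %d sequences (gap filter kept %d), L = %d\n",
              x$counts[["context"]], x$counts[["input"]],
              x$counts[["after_gap_filter"]], nrow(x$contact_map)))
  cat(sprintf("  scanned: %d pairs, %d mutants; backend: %s\n",
              x$counts[["pairs_scanned"]], x$counts[["mutants_scored"]],
              x$backend))
  cat(sprintf("  wild-type Hamiltonian: %.6f\n", x$wt_hamiltonian))
  cat("Top variants (lower Hamiltonian = predicted more stable):\n")
  show <- utils::head(x$variants[, c("rank", "label", "probability",
                                     "hamiltonian", "delta_vs_wildtype")],
                      n)
  print(show, row.names = FALSE, digits = 7)
  invisible(x)
}

#' @export
summary.zsh <- function(object, ...) {
  s <- list(
    counts = object$counts,
    config = object$config,
    backend = object$backend,
    wt_hamiltonian = object$wt_hamiltonian,
    n_variants = nrow(object$variants),
    best = object$variants[1L, , drop = FALSE],
    delta_range = range(object$variants$delta_vs_wildtype)
  )
  class(s) <- "summary.zsh"
  s
}

#' @export
print.summary.zsh <- function(x, ...) {
  cat("Zero-shot Hamiltonian scan summary\n")
  cat(sprintf("  backend %s; parameters: gap filter %.2f, context %d, ",
              x$backend, x$config$max_gap_ratio, x$config$context_size))
  cat(sprintf("top pairs %d, top variants %d\n",
              x$config$top_pairs, x$config$top_variants))
  cat(sprintf("  sequences: %d in, %d after gap filter, %d in context\n",
              x$counts[["input"]], x$counts[["after_gap_filter"]],
              x$counts[["context"]]))
  cat(sprintf("  mutants scored: %d over %d pairs\n",
              x$counts[["mutants_scored"]], x$counts[["pairs_scanned"]]))
  cat(sprintf("  wild-type Hamiltonian %.6f; best variant %s (H = %.6f, delta = %.6f)\n",
              x$wt_hamiltonian, x$best$label, x$best$hamiltonian,
              x$best$delta_vs_wildtype))
  cat(sprintf("  delta_vs_wildtype range among reported variants: [%.6f, %.6f]\n",
              x$delta_range[1L], x$delta_range[2L]))
  invisible(x)
}

#' @export
coef.zsh <- function(object, ...) {
  stats::setNames(object$variants$hamiltonian, object$variants$label)
}

#' Plot the contact map of a scan
#'
#' Draws the stage-one contact map as an image with the selected pairs
#' overplotted; an at-a-glance check of where the design signal lives.
#'
#' @param x A `zsh` object.
#' @param n_pairs Number of top pairs to mark, default all selected.
#' @param ... Passed to [graphics::image()].
#' @export
plot.zsh <- function(x, n_pairs = nrow(x$pairs), ...) {
  L <- nrow(x$contact_map)
  graphics::image(seq_len(L), seq_len(L), unclass(x$contact_map),
                  xlab = "position", ylab = "position",
                  main = "contact map (selected pairs marked)", ...)
  top <- utils::head(x$pairs, n_pairs)
  graphics::points(top$i, top$j, pch = 0, cex = 1.1)
  graphics::points(top$j, top$i, pch = 0, cex = 1.1)
  invisible(x)
}
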