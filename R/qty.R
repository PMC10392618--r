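#' Apply the QTY code to a protein
#'
#' Within each transmembrane segment, the four hydrophobic residues are
#' replaced by neutral polar residues of near-identical side-chain shape:
#' leucine by glutamine (L->Q), isoleucine and valine by threonine (I->T,
#' V->T), and phenylalanine by tyrosine (F->Y). Residues outside TM segments
#' — and every other residue type, including M, W and A — are untouched, so
#' the variant has exactly the native length and the operation is idempotent
#' (Q, T, Y are not in the substitution domain).
#'
#' @param record a \code{\link{protein_record}} (native sequence).
#' @param topology a \code{\link{tm_topology}} valid for the record's length.
#' @param whole_sequence if TRUE, substitute over the full sequence ignoring
#'   the topology (experimentation only; default FALSE).
#' @return an object of class \code{qty_variant}: the native record, the
#'   variant sequence, the topology, a data frame of substitution events
#'   (position, native_aa, variant_aa, segment_label) in ascending position
#'   order, and the overall / transmembrane variation percentages (half-up
#'   rounded to 2 decimals).
#' @examples
#' rec <- protein_record("toy", "KKLIVFKK")
#' top <- tm_topology(data.frame(start = 3, end = 6))
#' apply_qty(rec, top)$variant_sequence  # "KKQTTYKK"
#' @export
apply_qty <- function(record, topology, whole_sequence = FALSE) {
  stopifnot(inherits(record, "protein_record"), inherits(topology, "tm_topology"))
  L <- nchar(record$sequence)
  if (nrow(topology$segments) > 0L && max(topology$segments$end) > L) {
    stop("topology extends beyond sequence length ", L, call. = FALSE)
  }
  chars <- strsplit(record$sequence, "")[[1]]
  mask <- if (whole_sequence) rep(TRUE, L) else tm_mask(topology, L)
  hit <- mask & chars %in% names(QTY_MAP)
  pos <- which(hit)
  variant <- chars
  variant[pos] <- QTY_MAP[chars[pos]]

  seg_label <- rep(NA_character_, L)
  s <- topology$segments
  for (i in seq_len(nrow(s))) seg_label[s$start[i]:s$end[i]] <- s$label[i]

  events <- data.frame(
    position = pos,
    native_aa = chars[pos],
    variant_aa = unname(variant[pos]),
    segment_label = seg_label[pos],
    stringsAsFactors = FALSE
  )
  n_tm <- tm_residue_count(topology)
  structure(
    list(
      native = record,
      variant_sequence = paste(variant, collapse = ""),
      topology = topology,
      events = events,
      overall_variation_pct = round_half_up(100 * nrow(events) / L, 2),
      tm_variation_pct = if (n_tm > 0L) {
        round_half_up(100 * nrow(events) / n_tm, 2)
      } else 0
    ),
    class = "qty_variant"
  )
}

#' @export
print.qty_variant <- function(x, ...) {
  cat(sprintf(
    "<qty_variant> %s: %d substitutions over %d aa (overall %.2f%%, TM %.2f%%)\n",
    x$native$id, nrow(x$events), nchar(x$native$sequence),
    x$overall_variation_pct, x$tm_variation_pct))
  invisible(x)
}

#' Overall and transmembrane variation rates
#'
#' Recomputes, from the event list, the fraction of all residues changed and
#' the fraction of transmembrane residues changed, as percentages half-up
#' rounded to 2 decimals. For a GLUT-like transporter the paper-style
#' expectation is roughly 17-27% overall and 44-50% within the membrane.
#'
#' @param variant a \code{qty_variant} from \code{\link{apply_qty}}.
#' @return named numeric vector \code{c(overall_pct=, tm_pct=)}.
#' @export
variation_rates <- function(variant) {
  stopifnot(inherits(variant, "qty_variant"))
  L <- nchar(variant$native$sequence)
  n_ev <- nrow(variant$events)
  n_tm <- tm_residue_count(variant$topology)
  if (n_tm == 0L && n_ev > 0L) {
    stop("variant has substitution events but zero TM residues", call. = FALSE)
  }
  c(overall_pct = round_half_up(100 * n_ev / L, 2),
    tm_pct = if (n_tm > 0L) round_half_up(100 * n_ev / n_tm, 2) else 0)
}

#' Water hydrogen-bond capacity gained by QTY substitution
#'
#' Each substitution adds the side-chain water hydrogen-bonding capacity of
#' the replacement residue: glutamine contributes four water hydrogen bonds
#' (two donors via its amide -NH2, two acceptors via the carbonyl oxygen);
#' the hydroxyls of threonine and tyrosine contribute three each (one donor,
#' two acceptors). The replaced aliphatic/aromatic side chains (L, I, V, F)
#' contribute none, so the gain equals the variant-side capacity.
#'
#' @param variant a \code{qty_variant}.
#' @return list with \code{per_event} (integer vector, one entry per
#'   substitution) and \code{total} (their sum).
#' @export
hbond_capacity_gain <- function(variant) {
  stopifnot(inherits(variant, "qty_variant"))
  per_event <- unname(HBOND_CAPACITY[variant$events$variant_aa])
  per_event <- as.integer(if (length(per_event) == 0L) integer(0) else per_event)
  list(per_event = per_event, total = sum(per_event))
}
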