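#' Molecular weight of a protein sequence
#'
#' Sum of average-isotopic residue masses plus one water, following the
#' ExPASy ProtParam convention, reported to 2 decimals. QTY substitutions
#' shift the mass only slightly: the largest per-event change is F->Y
#' (+15.999 Da), so native and variant differ by at most a few hundred
#' daltons.
#'
#' @param seq amino-acid sequence (canonical alphabet).
#' @return molecular weight in daltons.
#' @examples
#' molecular_weight("G")     # 75.07
#' molecular_weight("QTTY")  # 511.53
#' @export
molecular_weight <- function(seq) {
  seq <- check_canonical(seq)
  chars <- strsplit(seq, "")[[1]]
  round_half_up(sum(AA_MASS_AVG[chars]) + WATER_MASS, 2)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the free N-terminus, free C-terminus and
#' the ionizable side chains (D, E, C, Y, H, K, R). Cysteines are treated as
#' free (no disulfide correction). Composition-only: permuting the sequence
#' does not change the result (terminal-residue identity aside).
#'
#' @param seq amino-acid sequence.
#' @param pH pH value or vector of values.
#' @param pka_set \code{"Bjellqvist"} (ExPASy-style, default) or
#'   \code{"EMBOSS"}.
#' @return net charge (same length as \code{pH}).
#' @export
net_charge <- function(seq, pH, pka_set = "Bjellqvist") {
  seq <- check_canonical(seq)
  pka <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  first <- chars[1]
  last <- chars[length(chars)]

  pk_nt <- if (first %in% names(pka$nterm)) pka$nterm[[first]] else pka$nterm_default
  pk_ct <- if (last %in% names(pka$cterm)) pka$cterm[[last]] else pka$cterm_default

  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))

  charge <- pos_frac(pk_nt) + neg_frac(pk_ct)
  for (aa in names(pka$positive)) {
    charge <- charge + counts[[aa]] * pos_frac(pka$positive[[aa]])
  }
  for (aa in names(pka$negative)) {
    charge <- charge + counts[[aa]] * neg_frac(pka$negative[[aa]])
  }
  charge
}

#' Isoelectric point
#'
#' pH at which the modelled net charge crosses zero, found by bisection over
#' pH 0..14 to |charge| < 1e-4 or a pH interval < 1e-4. Q and T carry no
#' ionizable side chain, so a QTY variant's pI can move only through added
#' tyrosines; variants without F->Y events keep the native pI exactly.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @examples
#' isoelectric_point("DDDD") < 7   # acidic
#' isoelectric_point("KKKK") > 7   # basic
#' @export
isoelectric_point <- function(seq, pka_set = "Bjellqvist") {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka_set)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence. Every QTY substitution
#' strictly lowers it (each mapped pair L->Q, I->T, V->T, F->Y decreases the
#' residue's hydropathy), which is the quantitative sense in which the
#' variant is "more hydrophilic".
#'
#' @param seq amino-acid sequence.
#' @return mean hydropathy (dimensionless).
#' @examples
#' gravy("LIVF")  #  3.825
#' gravy("QTTY")  # -1.55
#' @export
gravy <- function(seq) {
  seq <- check_canonical(seq)
  mean(KD_SCALE[strsplit(seq, "")[[1]]])
}

#' Windowed hydropathy profile
#'
#' Centred sliding-window means of the Kyte-Doolittle values; the profile has
#' \code{L - window + 1} points (one per valid window centre).
#'
#' @param seq amino-acid sequence with \code{nchar(seq) >= window}.
#' @param window odd window length (default 19).
#' @return numeric vector of window means.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  seq <- check_canonical(seq)
  stopifnot(window %% 2 == 1, window >= 1)
  L <- nchar(seq)
  if (L < window) {
    stop(sprintf("sequence length %d shorter than window %d", L, window),
         call. = FALSE)
  }
  h <- KD_SCALE[strsplit(seq, "")[[1]]]
  v <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  v[!is.na(v)]
}

#' Bundle of sequence properties
#'
#' Length, molecular weight, isoelectric point, GRAVY and the windowed
#' hydropathy profile for one sequence — the per-protein quantities reported
#' alongside each native/variant alignment.
#'
#' @inheritParams hydropathy_profile
#' @param pka_set pKa set for the pI calculation.
#' @return object of class \code{sequence_properties}.
#' @export
sequence_properties <- function(seq, window = 19, pka_set = "Bjellqvist") {
  seq <- check_canonical(seq)
  structure(
    list(
      length = nchar(seq),
      mw = molecular_weight(seq),
      pi = isoelectric_point(seq, pka_set),
      gravy = gravy(seq),
      profile = if (nchar(seq) >= window) hydropathy_profile(seq, window) else numeric(0)
    ),
    class = "sequence_properties"
  )
}

#' @export
print.sequence_properties <- function(x, ...) {
  cat(sprintf("<sequence_properties> %d aa | MW %.2f Da | pI %.2f | GRAVY %+.3f\n",
              x$length, x$mw, x$pi, x$gravy))
  invisible(x)
}

#' Native-versus-variant characteristics table
#'
#' One row per protein with the columns of the standard comparison layout:
#' id, length, MW_native, MW_QTY, pI_native, pI_QTY, overall_pct, TM_pct.
#'
#' @param variants list of \code{qty_variant} objects.
#' @param pka_set pKa set for pI.
#' @return data frame, one row per variant.
#' @export
properties_table <- function(variants, pka_set = "Bjellqvist") {
  if (inherits(variants, "qty_variant")) variants <- list(variants)
  rows <- lapply(variants, function(v) {
    rates <- variation_rates(v)
    data.frame(
      id = v$native$id,
      length = nchar(v$native$sequence),
      MW_native = molecular_weight(v$native$sequence),
      MW_QTY = molecular_weight(v$variant_sequence),
      pI_native = round_half_up(isoelectric_point(v$native$sequence, pka_set), 2),
      pI_QTY = round_half_up(isoelectric_point(v$variant_sequence, pka_set), 2),
      overall_pct = rates[["overall_pct"]],
      TM_pct = rates[["tm_pct"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
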