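# Seeded generator of synthetic proteomes, motif benchmarks and variant sets
# with the statistical structure the method assumes: an aromatic anchor at
# window offset 0, an aliphatic anchor at +3, acidic/hydroxyl-enriched inner
# flanks, and negatives arising as chance regex matches in background
# sequence. Everything is deterministic given the seed, so the whole pipeline
# is testable without any external data.

# window index (1..18) <-> motif offset (-7..+10); anchors at offsets 0 and +3
ANCHOR0_IDX <- 8L
ANCHOR3_IDX <- 11L
FLANK_ENRICHED_IDX <- c(4:7, 9:10)  # offsets -4..-1, +1, +2

#' Background amino-acid frequencies
#'
#' `"proteome"` (the default used by the generator) is the average
#' composition of reviewed protein sequences; it makes tryptophan rare
#' (~1%), so chance regex cores are mostly F/Y-anchored while true motifs
#' are W-enriched, as in real proteomes. `"uniform"` gives every residue
#' probability 1/20, which keeps null behaviour analytically simple but
#' removes most of the anchor's class signal.
#'
#' @param kind `"proteome"` or `"uniform"`.
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
aa_background <- function(kind = c("proteome", "uniform")) {
  kind <- match.arg(kind)
  aa <- aa_canonical()
  if (kind == "uniform") return(stats::setNames(rep(1 / 20, 20), aa))
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  f <- f[aa]
  f / sum(f)
}

#' Per-position emission model for synthetic motif windows
#'
#' Builds the 18 categorical distributions over the 20 canonical residues
#' from which positive windows are sampled. At full signal the anchor at
#' offset 0 draws W/F/Y (0.5/0.3/0.2), the anchor at +3 draws L/I/V
#' (0.4/0.3/0.3), and the inner flanks (offsets -4..-1, +1, +2) are enriched
#' for D/E/S/T (0.15 each); remaining positions follow the background.
#' `signal_strength` interpolates linearly towards the background; the
#' anchors interpolate towards the background restricted to their residue
#' class, so generated windows always match the canonical regex.
#'
#' @param signal_strength Value in \[0, 1\]; 0 gives pure background (anchors
#'   uniform within their class), 1 the full motif model.
#' @param background Named numeric vector of background residue frequencies
#'   over the 20 canonical amino acids; defaults to [aa_background()]
#'   (`"proteome"` composition).
#' @return A 18 x 20 matrix of probabilities, rows summing to 1.
#' @export
emission_model <- function(signal_strength = 1,
                           background = NULL) {
  stopifnot(signal_strength >= 0, signal_strength <= 1)
  aa <- aa_canonical()
  if (is.null(background)) {
    background <- aa_background()
  }
  stopifnot(setequal(names(background), aa),
            abs(sum(background) - 1) < 1e-8)
  background <- background[aa]

  restrict <- function(p, set) {
    q <- ifelse(names(p) %in% set, p, 0)
    q / sum(q)
  }
  motif <- matrix(rep(background, each = WINDOW_LEN), nrow = WINDOW_LEN,
                  dimnames = list(NULL, aa))
  motif[ANCHOR0_IDX, ] <- 0
  motif[ANCHOR0_IDX, c("W", "F", "Y")] <- c(0.5, 0.3, 0.2)
  motif[ANCHOR3_IDX, ] <- 0
  motif[ANCHOR3_IDX, c("L", "I", "V")] <- c(0.4, 0.3, 0.3)
  flank <- rep(0.4 / 16, 20)
  names(flank) <- aa
  flank[c("D", "E", "S", "T")] <- 0.15
  for (j in FLANK_ENRICHED_IDX) motif[j, ] <- flank

  s <- signal_strength
  out <- matrix(NA_real_, WINDOW_LEN, 20, dimnames = list(NULL, aa))
  for (j in seq_len(WINDOW_LEN)) {
    base <- if (j == ANCHOR0_IDX) {
      restrict(background, c("F", "W", "Y"))
    } else if (j == ANCHOR3_IDX) {
      restrict(background, c("L", "I", "V"))
    } else {
      background
    }
    out[j, ] <- s * motif[j, ] + (1 - s) * base
  }
  out
}

sample_window <- function(em) {
  aa <- colnames(em)
  paste(vapply(seq_len(nrow(em)),
               function(j) sample(aa, 1L, prob = em[j, ]), character(1)),
        collapse = "")
}

sample_background <- function(len, background) {
  paste(sample(names(background), len, replace = TRUE, prob = background),
        collapse = "")
}

#' Generate a synthetic proteome with a planted motif benchmark
#'
#' Background proteins are i.i.d. residue strings; `n_pos` positive windows
#' sampled from [emission_model()] are planted at interior, non-overlapping
#' sites spread over the proteins, and `n_nearmiss` additional "near-miss"
#' windows (motif-like flanks but a proline in place of the aromatic anchor,
#' so no core) are planted as substrates for gain variants. The benchmark is
#' then assembled by [build_benchmark()], so negatives are the chance regex
#' matches in the same proteins.
#'
#' @param n_pos Number of planted positive motifs.
#' @param n_proteins Number of proteins.
#' @param protein_length Length of every protein.
#' @param signal_strength Motif signal in \[0, 1\] (see [emission_model()]).
#' @param n_nearmiss Number of planted near-miss (anchorless) windows.
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @param background Optional background frequency vector; defaults to
#'   [aa_background()].
#' @return A list of class `lir_simulation`: `proteins`, `annotations`,
#'   `benchmark`, `nearmiss` (tibble of accession/position of the planted
#'   anchorless anchors), `emission` and `seed`.
#' @export
generate_benchmark <- function(n_pos = 127L, n_proteins = 105L,
                               protein_length = 400L, signal_strength = 1,
                               n_nearmiss = 20L, seed = 1L,
                               background = NULL) {
  stopifnot(n_pos >= 2L, n_proteins >= 1L, protein_length >= 60L)
  if (is.null(background)) background <- aa_background()
  em <- emission_model(signal_strength, background)

  withr::with_seed(seed, {
    proteins <- tibble::tibble(
      accession = sprintf("SYN%04d", seq_len(n_proteins)),
      sequence = vapply(seq_len(n_proteins),
                        function(i) sample_background(protein_length, background),
                        character(1))
    )
    # spread the planted windows over proteins; a protein may host several
    host <- sort(rep_len(seq_len(n_proteins), n_pos + n_nearmiss))
    kind <- sample(rep(c("pos", "miss"), c(n_pos, n_nearmiss)))
    slots_per <- max(table(host))
    ann <- vector("list", length(host))
    nearmiss <- vector("list", length(host))
    for (p in unique(host)) {
      idx <- which(host == p)
      # non-overlapping interior window slots, >= 18 apart
      usable <- seq(FLANK + 1L, protein_length - FLANK - CORE_LEN - WINDOW_LEN,
                    by = WINDOW_LEN + 2L)
      starts <- sort(sample(usable, length(idx)))
      sq <- proteins$sequence[p]
      for (k in seq_along(idx)) {
        w <- sample_window(em)
        if (kind[idx[k]] == "miss") {
          # remove the aromatic anchor so the window has no core of its own
          substr(w, ANCHOR0_IDX, ANCHOR0_IDX) <- "P"
        }
        core_start <- starts[k] + FLANK  # window begins at starts[k]
        substr(sq, starts[k], starts[k] + WINDOW_LEN - 1L) <- w
        if (kind[idx[k]] == "pos") {
          ann[[idx[k]]] <- tibble::tibble(
            accession = proteins$accession[p], core_start = core_start,
            motif_class = "cLIR")
        } else {
          nearmiss[[idx[k]]] <- tibble::tibble(
            accession = proteins$accession[p], anchor_pos = core_start)
        }
      }
      proteins$sequence[p] <- sq
    }
    annotations <- dplyr::bind_rows(ann)
    nearmiss <- dplyr::bind_rows(nearmiss)
  })

  structure(
    list(proteins = proteins,
         annotations = annotations,
         benchmark = build_benchmark(proteins, annotations),
         nearmiss = nearmiss,
         emission = em,
         signal_strength = signal_strength,
         seed = as.integer(seed)),
    class = "lir_simulation"
  )
}

#' @export
print.lir_simulation <- function(x, ...) {
  cat("<lir_simulation>", nrow(x$proteins), "proteins,",
      sum(x$benchmark$label == "positive"), "positives,",
      sum(x$benchmark$label == "negative"), "negatives, signal =",
      x$signal_strength, "\n")
  invisible(x)
}

# prototypical window: modal aromatic anchor (W) unless anchorless, and at
# least 3 of the 6 enriched flank offsets carrying D/E/S/T - the clear-cut
# exemplars that planted gain/loss events are staged on
is_prototypical <- function(window_seq, require_anchor = TRUE) {
  anchor_ok <- !require_anchor |
    substr(window_seq, ANCHOR0_IDX, ANCHOR0_IDX) == "W"
  dest <- vapply(window_seq, function(w) {
    sum(strsplit(w, "")[[1]][FLANK_ENRICHED_IDX] %in% c("D", "E", "S", "T"))
  }, integer(1))
  anchor_ok & dest >= 3L
}

#' Generate variants with known gain/loss/neutral truth
#'
#' Loss variants substitute the aromatic anchor of a planted positive motif
#' with a residue outside both anchor classes, destroying the core. Gain
#' variants mutate the proline placeholder of a planted near-miss window to
#' W, creating a core with motif-grade flanks. Neutral variants are split
#' between "flank" neutrals, which hit the non-informative window offsets
#' (the outer flanks, background-distributed under the emission model) of
#' existing cores - drawn half from positive and half from chance negative
#' cores, so weak-effect near-diagonal pairs dominate the pair density at
#' every score level, as they do in a real mutation corpus - and "far"
#' neutrals placed outside every candidate window. The defaults keep planted
#' gain/loss events a rare minority of the pair mass, mirroring a corpus in
#' which almost all mutations barely move the score.
#'
#' @param sim A `lir_simulation` from [generate_benchmark()].
#' @param n_loss,n_gain,n_neutral Variant counts per truth class.
#' @param flank_fraction Fraction of neutrals of the "flank" kind (the rest
#'   are "far").
#' @param seed Integer seed.
#' @return Tibble of variants with columns `accession`, `position`, `ref_aa`,
#'   `alt_aa`, `truth` (`loss`/`gain`/`neutral`), `subtype`, `core_start`
#'   (NA for far neutrals).
#' @export
generate_variants <- function(sim, n_loss = 10L, n_gain = 6L,
                              n_neutral = 6000L, flank_fraction = 0.85,
                              seed = 1L) {
  stopifnot(inherits(sim, "lir_simulation"))
  pos <- dplyr::filter(sim$benchmark, .data$label == "positive")
  neg <- dplyr::filter(sim$benchmark, .data$label == "negative")
  seq_of <- stats::setNames(sim$proteins$sequence, sim$proteins$accession)
  safe_alt <- setdiff(aa_canonical(), c("F", "W", "Y", "L", "I", "V"))

  # stage planted events on prototypical windows only (the analog of a
  # strong, experimentally validated motif)
  pos_hosts <- pos[is_prototypical(pos$window_seq), ]
  nm <- sim$nearmiss
  if (nrow(nm) > 0L) {
    nm_window <- vapply(seq_len(nrow(nm)), function(i) {
      extract_window(seq_of[[nm$accession[i]]], nm$anchor_pos[i])
    }, character(1))
    nm <- nm[is_prototypical(nm_window, require_anchor = FALSE), ]
  }
  if (n_loss > nrow(pos_hosts)) {
    stop("not enough prototypical planted motifs to host n_loss")
  }
  if (n_gain > nrow(nm)) {
    stop("not enough prototypical near-miss windows to host n_gain")
  }

  withr::with_seed(seed, {
    loss_rows <- pos_hosts[sample.int(nrow(pos_hosts), n_loss), ]
    loss <- tibble::tibble(
      accession = loss_rows$accession,
      position = loss_rows$core_start,
      ref_aa = substr(loss_rows$core_seq, 1L, 1L),
      alt_aa = sample(setdiff(safe_alt, "P"), n_loss, replace = TRUE),
      truth = "loss", subtype = "anchor",
      core_start = loss_rows$core_start
    )

    gain_rows <- nm[sample.int(nrow(nm), n_gain), ]
    gain <- tibble::tibble(
      accession = gain_rows$accession,
      position = gain_rows$anchor_pos,
      ref_aa = "P", alt_aa = "W",
      truth = "gain", subtype = "anchor_creation",
      core_start = gain_rows$anchor_pos
    )

    # flank neutrals: non-informative window offsets (outer flanks, which the
    # emission model leaves at background), half on positive cores and half
    # on chance negative cores
    n_flank <- as.integer(round(n_neutral * flank_fraction))
    informative_off <- c(0L, 3L, FLANK_ENRICHED_IDX - ANCHOR0_IDX)
    flank_off <- setdiff(-FLANK:(FLANK + CORE_LEN - 1L), informative_off)
    draw_flank <- function(cores, n_want) {
      out <- NULL
      tries <- 0L
      while (is.null(out) || nrow(out) < n_want) {
        tries <- tries + 1L
        if (tries > 200L) stop("could not place enough flank neutrals")
        r <- cores[sample.int(nrow(cores), n_want, replace = TRUE), ]
        p <- r$core_start + sample(flank_off, n_want, replace = TRUE)
        len <- nchar(seq_of[r$accession])
        ok <- p >= 1L & p <= len
        ref <- substr(seq_of[r$accession], p, p)
        ok <- ok & !(ref %in% c("F", "W", "Y", "L", "I", "V"))
        cand <- tibble::tibble(
          accession = r$accession[ok], position = p[ok], ref_aa = ref[ok],
          alt_aa = sample(safe_alt, sum(ok), replace = TRUE),
          truth = "neutral", subtype = "flank", core_start = r$core_start[ok])
        cand <- cand[cand$ref_aa != cand$alt_aa, ]
        # a site may host several alternate alleles, as in real corpora
        out <- dplyr::distinct(dplyr::bind_rows(out, cand),
                               .data$accession, .data$position, .data$alt_aa,
                               .keep_all = TRUE)
      }
      out[seq_len(n_want), ]
    }
    n_flank_pos <- n_flank %/% 2L
    flank <- dplyr::bind_rows(draw_flank(pos, n_flank_pos),
                              draw_flank(neg, n_flank - n_flank_pos))
    flank <- dplyr::distinct(flank, .data$accession, .data$position,
                             .data$alt_aa, .keep_all = TRUE)
    n_flank <- nrow(flank)

    # far neutrals: outside every candidate window of every original core
    n_far <- n_neutral - n_flank
    far <- NULL
    tries <- 0L
    while (is.null(far) || nrow(far) < n_far) {
      tries <- tries + 1L
      if (tries > 200L) stop("could not place enough far neutrals")
      acc <- sample(sim$proteins$accession, n_far, replace = TRUE)
      p <- vapply(acc, function(a) sample.int(nchar(seq_of[[a]]), 1L),
                  integer(1))
      keep <- vapply(seq_along(acc), function(i) {
        cs <- scan_clir_cores(seq_of[[acc[i]]])
        all(p[i] < cs - 10L | p[i] > cs + 7L)
      }, logical(1))
      ref <- substr(seq_of[acc], p, p)
      keep <- keep & !(ref %in% c("F", "W", "Y", "L", "I", "V"))
      cand <- tibble::tibble(
        accession = acc[keep], position = p[keep], ref_aa = ref[keep],
        alt_aa = sample(safe_alt, sum(keep), replace = TRUE),
        truth = "neutral", subtype = "far", core_start = NA_integer_)
      cand <- cand[cand$ref_aa != cand$alt_aa, ]
      far <- dplyr::distinct(dplyr::bind_rows(far, cand),
                             .data$accession, .data$position, .data$alt_aa,
                             .keep_all = TRUE)
    }
    far <- far[seq_len(n_far), ]
  })

  out <- dplyr::bind_rows(loss, gain, flank, far)
  out$position <- as.integer(out$position)
  out
}
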