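# residues whose sampling weight rises (+) or falls (-) in positive-pair
# proteins under a composition shift; fixed so the planted signal is stable
SHIFT_UP <- strsplit("ACDEFGHIKL", "")[[1]]
SHIFT_DOWN <- strsplit("MNPQRSTVWY", "")[[1]]

#' Parameters for the synthetic interaction-data generator
#'
#' Defaults state a world mirroring the benchmark composition the method
#' was built for: 850 positive and 2554 negative pairs, aptamers of
#' 20-80 nt, proteins of 100-400 aa (all longer than lambda = 30).
#' Positives carry a planted DNA motif (on average `motif_strength`
#' extra copies per positive aptamer, Poisson-drawn and capped by the
#' sequence's capacity) and a residue-composition shift in their
#' proteins (log-weight `+composition_shift/2` for ACDEFGHIKL,
#' `-composition_shift/2` for the rest); negatives are uniform
#' background paired at random with no overlap with the positives.
#'
#' @param n_pos,n_neg class sizes (defaults 850 / 2554).
#' @param aptamer_length,protein_length inclusive length ranges.
#' @param motif planted DNA k-mer (default "ACGT"; must not overlap its
#'   own shifts, which holds for the default).
#' @param motif_strength expected extra motif copies per positive aptamer.
#' @param composition_shift log-enrichment scale for positive proteins.
#' @param noise label-flip probability after pairing (default 0).
#' @param seed integer seed.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(n_pos = 850L, n_neg = 2554L,
                             aptamer_length = c(20L, 80L),
                             protein_length = c(100L, 400L),
                             motif = "ACGT", motif_strength = 0,
                             composition_shift = 0, noise = 0, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(aptamer_length) == 2,
            length(protein_length) == 2, motif_strength >= 0,
            noise >= 0, noise <= 1)
  motif <- toupper(motif)
  validate_residues(motif, "motif", "dna")
  k <- nchar(motif)
  if (aptamer_length[1] < 3 * k - 2) {
    stop("minimum aptamer length ", aptamer_length[1],
         " cannot host an interior motif copy (need >= ", 3 * k - 2, ")")
  }
  if (protein_length[1] <= 30) {
    stop("minimum protein length must exceed lambda = 30")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 aptamer_length = as.integer(aptamer_length),
                 protein_length = as.integer(protein_length),
                 motif = motif, motif_strength = motif_strength,
                 composition_shift = composition_shift, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Named generator presets
#'
#' `null`: no planted signal (exchangeable classes); `weak`: one extra
#' motif copy and a 0.2 composition shift; `strong`: three extra copies
#' and a 0.5 shift. `n_total` is split between the classes in the
#' benchmark 850:2554 proportion.
#'
#' @param preset `"null"`, `"weak"` or `"strong"`.
#' @param n_total total number of pairs (default 3404).
#' @param seed integer seed.
#' @return a [synthetic_params()] object.
#' @export
synthetic_preset <- function(preset = c("null", "weak", "strong"),
                             n_total = 3404L, seed = 1L) {
  preset <- match.arg(preset)
  n_pos <- max(1L, round(n_total * 850 / 3404))
  sig <- switch(preset,
                null = c(0, 0), weak = c(1, 0.2), strong = c(3, 0.5))
  synthetic_params(n_pos = n_pos, n_neg = n_total - n_pos,
                   motif_strength = sig[1], composition_shift = sig[2],
                   seed = seed)
}

rand_string <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

shift_probs <- function(shift) {
  w <- ifelse(AA_ORDER %in% SHIFT_UP, exp(shift / 2), exp(-shift / 2))
  w / sum(w)
}

# choose c interior motif start positions with pairwise gaps >= 2k-1 so
# each planted copy disturbs a disjoint window set; capacity floor(W/(2k-1))
plant_motif <- function(s, motif, strength) {
  k <- nchar(motif)
  L <- nchar(s)
  W <- L - k + 1L
  g <- 2L * k - 2L
  a <- k
  b <- L - 2L * k + 2L
  c_max <- if (b < a) 0L else floor((b - a + 1L + g) / (g + 1L))
  cc <- min(rpois(1L, strength), c_max)
  if (cc == 0L) return(s)
  y <- sort(sample.int(b - a + 1L - (cc - 1L) * g, cc))
  pos <- a + y - 1L + (seq_len(cc) - 1L) * g
  for (p in pos) substr(s, p, p + k - 1L) <- motif
  s
}

#' Generate a synthetic aptamer-protein interaction dataset
#'
#' Positive pairs are motif-enriched aptamers matched 1:1 with
#' composition-shifted proteins; negative pairs are uniform background
#' sequences paired 1:1 (each synthetic sequence is used once, so no
#' negative pair duplicates a positive one). Labels are flipped with
#' probability `noise` afterwards. Byte-identical output under the same
#' seed.
#'
#' @param params a [synthetic_params()].
#' @param dir optional directory; when given, writes `aptamers.fasta`,
#'   `proteins.fasta` and `pairs.csv` in the formats the readers consume.
#' @return an [interaction_dataset()] (invisibly carries `dir` as the
#'   `"path"` attribute when files were written).
#' @export
generate_dataset <- function(params, dir = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  ds <- with_seed(p$seed, {
    n <- p$n_pos + p$n_neg
    # sample.int form avoids the sample() scalar pitfall for degenerate ranges
    apt_len <- p$aptamer_length[1] +
      sample.int(diff(p$aptamer_length) + 1L, n, replace = TRUE) - 1L
    prot_len <- p$protein_length[1] +
      sample.int(diff(p$protein_length) + 1L, n, replace = TRUE) - 1L
    apt <- character(n)
    prot <- character(n)
    pos_probs <- shift_probs(p$composition_shift)
    for (i in seq_len(n)) {
      s <- rand_string(apt_len[i], DNA_BASES)
      if (i <= p$n_pos && p$motif_strength > 0) {
        s <- plant_motif(s, p$motif, p$motif_strength)
      }
      apt[i] <- s
      prot[i] <- rand_string(prot_len[i], AA_ORDER,
                             if (i <= p$n_pos) pos_probs else NULL)
    }
    names(apt) <- sprintf("apt%04d", seq_len(n))
    names(prot) <- sprintf("prot%04d", seq_len(n))
    label <- rep(c(1L, 0L), c(p$n_pos, p$n_neg))
    if (p$noise > 0) {
      flip <- runif(n) < p$noise
      label[flip] <- 1L - label[flip]
    }
    interaction_dataset(
      data.frame(aptamer_id = names(apt), protein_id = names(prot),
                 label = label, stringsAsFactors = FALSE),
      seq_set(apt, "dna"), seq_set(prot, "protein"))
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(ds$aptamers, file.path(dir, "aptamers.fasta"))
    write_fasta(ds$proteins, file.path(dir, "proteins.fasta"))
    write_pair_table(ds, file.path(dir, "pairs.csv"))
    attr(ds, "path") <- dir
  }
  ds
}

#' Expected planted-signal summary
#'
#' Closed-form expectations of the class differences the generator
#' plants, for parameter-recovery tests. The motif-frequency difference
#' per sliding window accounts for the Poisson copy count truncated at
#' each length's capacity and for the background windows a planted copy
#' overwrites (factor `1 - (2k-1)/4^k`, assuming a motif without
#' self-overlap); `first_order` is the simpler strength/(L-k+1) value.
#' The AAC difference is the exact softmax composition shift.
#'
#' @param params a [synthetic_params()].
#' @return list: `expected_kmer_freq_diff`, `first_order`,
#'   `expected_aac_diff` (named 20-vector), `motif`, `k`.
#' @export
describe_signal <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  k <- nchar(p$motif)
  g <- 2L * k - 2L
  lens <- p$aptamer_length[1]:p$aptamer_length[2]
  per_len <- vapply(lens, function(L) {
    W <- L - k + 1L
    b <- L - 2L * k + 2L
    c_max <- if (b < k) 0L else floor((b - k + 1L + g) / (g + 1L))
    if (c_max == 0L || p$motif_strength == 0) return(0)
    # E[min(Poisson(strength), c_max)]
    j <- 0:c_max
    pj <- dpois(j, p$motif_strength)
    ec <- sum(j * pj) + c_max * (1 - sum(pj))
    ec * (1 - (2 * k - 1) / 4^k) / W
  }, 0)
  aac <- if (p$composition_shift == 0) {
    stats::setNames(rep(0, 20), AA_ORDER)
  } else {
    stats::setNames(shift_probs(p$composition_shift) - 1 / 20, AA_ORDER)
  }
  mean_W <- mean(lens) - k + 1
  list(expected_kmer_freq_diff = mean(per_len),
       first_order = p$motif_strength / mean_W,
       expected_aac_diff = aac, motif = p$motif, k = k)
}
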