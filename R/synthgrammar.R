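# Synthetic antibody grammar: a desk-scale stand-in for repertoire data.
#
# The generator emulates the structural premise of Fv sequences - conserved
# frameworks, variable CDRs with the highest entropy in CDR-H3 - using a
# multi-family template model (families stand in for IGHV/IGLV germline
# genes).  Frameworks are family templates with i.i.d. substitutions at a low
# rate; CDR1/CDR2 are drawn from small per-family motif sets; CDR3 has
# family-determined first/last anchor residues and interior residues drawn
# from a family-biased frequency vector.  Two rules are planted for the
# downstream heads: a heavy-light family compatibility map (reinforced by a
# shared framework-3 key residue) and a length-3 CDR3 binding motif at a
# fixed offset.

#' Grammar configuration
#'
#' Defaults state the generator's world: 7 families (mirroring IGHV1..IGHV7),
#' typical Fv framework proportions (heavy FR lengths 25/17/38/11) so that a
#' 0-3 residue terminal truncation touches only FR1/FR4, framework
#' substitution rate 0.02, CDR-H3 length uniform on 8..20, and a fixed-length
#' (10) CDR3 mutant library with 5% label noise for the binding task.
#'
#' @param n_families number of heavy (and light) chain families.
#' @param heavy_fr_len,light_fr_len framework lengths FR1..FR4.
#' @param heavy_cdr_len,light_cdr_len CDR1/CDR2 lengths.
#' @param heavy_cdr3_range,light_cdr3_range inclusive CDR3 length range.
#' @param fr_sub_rate per-position framework substitution probability.
#' @param n_cdr_motifs motifs per family per CDR1/CDR2.
#' @param n_favored CDR3-favored residues per family.
#' @param favored_mass total CDR3 probability mass on the favored residues.
#' @param binding_cdr3_len fixed CDR3 length of the binding library.
#' @param binding_motif_len,binding_motif_offset planted motif size and
#'   0-based offset within CDR3.
#' @param binding_label_noise label flip probability.
#' @param seed integer seed making [build_grammar()] deterministic.
#' @return object of class \code{abmlm_grammar_config}.
#' @export
grammar_config <- function(n_families = 7L,
                           heavy_fr_len = c(25L, 17L, 38L, 11L),
                           light_fr_len = c(23L, 15L, 32L, 10L),
                           heavy_cdr_len = c(8L, 8L),
                           light_cdr_len = c(6L, 3L),
                           heavy_cdr3_range = c(8L, 20L),
                           light_cdr3_range = c(8L, 12L),
                           fr_sub_rate = 0.02,
                           n_cdr_motifs = 2L,
                           n_favored = 3L,
                           favored_mass = 0.6,
                           binding_cdr3_len = 10L,
                           binding_motif_len = 3L,
                           binding_motif_offset = 3L,
                           binding_label_noise = 0.05,
                           seed = 42L) {
  fail_if(n_families < 1L, "need at least one family")
  fail_if(fr_sub_rate < 0 || fr_sub_rate >= 1, "fr_sub_rate must be in [0, 1)")
  fail_if(binding_motif_offset + binding_motif_len > binding_cdr3_len,
          "binding motif does not fit in the CDR3 window")
  out <- as.list(environment())
  class(out) <- "abmlm_grammar_config"
  out
}

#' @noRd
.rand_seq <- function(n, rng) {
  paste0(with_rng(rng, sample(AA_CANONICAL, n, replace = TRUE)), collapse = "")
}

#' Build a grammar from its configuration
#'
#' Deterministic given \code{cfg$seed}: emits per-family framework templates,
#' CDR motif sets, CDR3 anchors and residue frequencies, and the two planted
#' rules.
#'
#' @param cfg a [grammar_config()].
#' @return object of class \code{abmlm_grammar}.
#' @export
build_grammar <- function(cfg) {
  rng <- new_rng(derive_seed(cfg$seed, "grammar"))
  make_side <- function(fr_len, cdr_len) {
    fams <- lapply(seq_len(cfg$n_families), function(f) {
      frs <- lapply(fr_len, function(n) .rand_seq(n, rng))
      motifs <- lapply(cdr_len, function(n) {
        base <- .rand_seq(n, rng)
        ms <- base
        while (length(ms) < cfg$n_cdr_motifs) {
          v <- strsplit(base, "")[[1]]
          p <- with_rng(rng, sample.int(n, 1L))
          v[p] <- with_rng(rng, sample(setdiff(AA_CANONICAL, v[p]), 1L))
          ms <- unique(c(ms, paste0(v, collapse = "")))
        }
        ms
      })
      favored <- with_rng(rng, sample(AA_CANONICAL, cfg$n_favored))
      freq <- stats::setNames(rep((1 - cfg$favored_mass) / (20 - cfg$n_favored), 20L),
                              AA_CANONICAL)
      freq[favored] <- cfg$favored_mass / cfg$n_favored
      anchors <- with_rng(rng, sample(AA_CANONICAL, 2L, replace = TRUE))
      list(fr = frs, motifs = motifs, cdr3_freq = freq, cdr3_anchor = anchors)
    })
    fams
  }
  heavy <- make_side(cfg$heavy_fr_len, cfg$heavy_cdr_len)
  light <- make_side(cfg$light_fr_len, cfg$light_cdr_len)

  # planted pairing rule: heavy family f pairs with light family f, and the
  # partners share a family key residue at fixed FR3 positions
  key_pos_h <- with_rng(rng, sample.int(cfg$heavy_fr_len[3], 1L)) - 1L
  key_pos_l <- with_rng(rng, sample.int(cfg$light_fr_len[3], 1L)) - 1L
  key_res <- with_rng(rng, sample(AA_CANONICAL, cfg$n_families, replace = TRUE))
  for (f in seq_len(cfg$n_families)) {
    substr(heavy[[f]]$fr[[3]], key_pos_h + 1L, key_pos_h + 1L) <- key_res[f]
    substr(light[[f]]$fr[[3]], key_pos_l + 1L, key_pos_l + 1L) <- key_res[f]
  }
  pairing <- list(map = seq_len(cfg$n_families),
                  key_pos_h = key_pos_h, key_pos_l = key_pos_l,
                  key_residue = key_res)

  binding <- list(motif = .rand_seq(cfg$binding_motif_len, rng),
                  offset = cfg$binding_motif_offset,
                  cdr3_len = cfg$binding_cdr3_len,
                  label_noise = cfg$binding_label_noise)

  out <- list(cfg = cfg, heavy = heavy, light = light,
              pairing = pairing, binding = binding)
  class(out) <- "abmlm_grammar"
  out
}

#' @noRd
.mutate_fr <- function(template, rate, rng) {
  if (rate <= 0) return(template)
  v <- strsplit(template, "")[[1]]
  hit <- with_rng(rng, stats::runif(length(v))) < rate
  if (any(hit)) {
    for (p in which(hit)) {
      v[p] <- with_rng(rng, sample(setdiff(AA_CANONICAL, v[p]), 1L))
    }
  }
  paste0(v, collapse = "")
}

#' @noRd
.sample_chain <- function(grammar, side, chain_type, rng, id,
                          family = NULL, cdr3_len = NULL, cdr3_seq = NULL) {
  cfg <- grammar$cfg
  if (is.null(family)) {
    family <- with_rng(rng, sample.int(cfg$n_families, 1L))
  }
  fam <- side[[family]]
  rng_range <- if (chain_type == "heavy") cfg$heavy_cdr3_range else cfg$light_cdr3_range
  frs <- vapply(fam$fr, .mutate_fr, character(1), rate = cfg$fr_sub_rate, rng = rng)
  cdr12 <- vapply(fam$motifs, function(ms) {
    with_rng(rng, ms[sample.int(length(ms), 1L)])
  }, character(1))
  if (is.null(cdr3_seq)) {
    if (is.null(cdr3_len)) {
      cdr3_len <- with_rng(rng, sample(rng_range[1]:rng_range[2], 1L))
    }
    inner <- if (cdr3_len > 2L) {
      paste0(with_rng(rng, sample(AA_CANONICAL, cdr3_len - 2L, replace = TRUE,
                                  prob = fam$cdr3_freq)), collapse = "")
    } else ""
    cdr3_seq <- paste0(fam$cdr3_anchor[1], inner, fam$cdr3_anchor[2])
  }
  segs <- c(frs[1], cdr12[1], frs[2], cdr12[2], frs[3], cdr3_seq, frs[4])
  lens <- nchar(segs)
  ends <- cumsum(lens)
  starts <- ends - lens
  annotated_chain(id, paste0(segs, collapse = ""), chain_type,
                  regions = region_annotation(starts, ends), family = family)
}

#' Sample one annotated heavy chain
#'
#' @param grammar an [build_grammar()] object.
#' @param rng stream.
#' @param id chain id.
#' @param family optional fixed family.
#' @return an [annotated_chain()] with exact ground-truth regions and a
#'   family label.
#' @export
sample_heavy <- function(grammar, rng, id = "H1", family = NULL) {
  .sample_chain(grammar, grammar$heavy, "heavy", rng, id, family = family)
}

#' Sample one annotated light chain
#' @inheritParams sample_heavy
#' @export
sample_light <- function(grammar, rng, id = "L1", family = NULL) {
  .sample_chain(grammar, grammar$light, "light", rng, id, family = family)
}

#' Sample an annotated corpus
#'
#' @param grammar grammar object.
#' @param n number of chains.
#' @param rng stream.
#' @param chain_type "heavy" or "light".
#' @param prefix id prefix.
#' @return list of annotated chains.
#' @export
sample_corpus <- function(grammar, n, rng, chain_type = "heavy", prefix = NULL) {
  fail_if(n < 1L, "n must be >= 1")
  if (is.null(prefix)) prefix <- if (chain_type == "heavy") "H" else "L"
  fn <- if (chain_type == "heavy") sample_heavy else sample_light
  lapply(seq_len(n), function(i) fn(grammar, rng, id = sprintf("%s%05d", prefix, i)))
}

#' Does a heavy-light pair satisfy the planted compatibility rule?
#'
#' @param grammar grammar object.
#' @param heavy,light annotated chains with family labels.
#' @return TRUE iff the light's family is allowed for the heavy's family.
#' @export
pairing_rule_check <- function(grammar, heavy, light) {
  grammar$pairing$map[heavy$family] == light$family
}

#' Sample a paired heavy-light dataset with a planted compatibility rule
#'
#' Every emitted positive satisfies the family map; the returned light pool
#' spans all families so that the identity-filtered negative sampling of the
#' pairing head is satisfiable by construction.
#'
#' @param grammar grammar object.
#' @param n number of positive pairs.
#' @param rng stream.
#' @param n_pool size of the light-chain pool (default 10 per family).
#' @return list with \code{pairs} (list of \code{list(heavy, light)}) and
#'   \code{light_pool} (list of light chains).
#' @export
sample_paired_dataset <- function(grammar, n, rng,
                                  n_pool = 10L * grammar$cfg$n_families) {
  fail_if(n < 1L, "n must be >= 1")
  pairs <- lapply(seq_len(n), function(i) {
    h <- sample_heavy(grammar, rng, id = sprintf("PH%05d", i))
    lf <- grammar$pairing$map[h$family]
    l <- sample_light(grammar, rng, id = sprintf("PL%05d", i), family = lf)
    list(heavy = h, light = l)
  })
  pool <- lapply(seq_len(n_pool), function(i) {
    fam <- ((i - 1L) %% grammar$cfg$n_families) + 1L
    sample_light(grammar, rng, id = sprintf("POOL%05d", i), family = fam)
  })
  list(pairs = pairs, light_pool = pool)
}

#' Sample a fixed-length CDR3 binding library with a planted motif
#'
#' Emulates a fixed-length CDR-H3 mutant library: every VH has the same CDR3
#' length; the label is 1 iff the planted motif occupies its fixed offset,
#' then flipped with the label-noise rate.  Class balance is ~1:1 by
#' construction (the motif is planted in half the draws; motif-bearing
#' negatives are rejection-sampled away).
#'
#' @param grammar grammar object.
#' @param n number of examples.
#' @param rng stream.
#' @return list of examples: \code{chain} (VH [annotated_chain()]),
#'   \code{cdr3_start}, \code{cdr3_end} (0-based half-open), \code{label},
#'   \code{clean_label} (pre-noise).
#' @export
sample_binding_dataset <- function(grammar, n, rng) {
  fail_if(n < 1L, "n must be >= 1")
  b <- grammar$binding
  motif_chars <- strsplit(b$motif, "")[[1]]
  lapply(seq_len(n), function(i) {
    fam_i <- with_rng(rng, sample.int(grammar$cfg$n_families, 1L))
    fam <- grammar$heavy[[fam_i]]
    plant <- with_rng(rng, stats::runif(1L)) < 0.5
    repeat {
      inner <- with_rng(rng, sample(AA_CANONICAL, b$cdr3_len - 2L, replace = TRUE,
                                    prob = fam$cdr3_freq))
      cdr3 <- c(fam$cdr3_anchor[1], inner, fam$cdr3_anchor[2])
      if (plant) {
        cdr3[(b$offset + 1L):(b$offset + nchar(b$motif))] <- motif_chars
        break
      }
      if (!identical(cdr3[(b$offset + 1L):(b$offset + nchar(b$motif))], motif_chars)) {
        break
      }
    }
    ch <- .sample_chain(grammar, grammar$heavy, "heavy", rng,
                        id = sprintf("B%05d", i), family = fam_i,
                        cdr3_seq = paste0(cdr3, collapse = ""))
    clean <- as.integer(plant)
    label <- clean
    if (with_rng(rng, stats::runif(1L)) < b$label_noise) label <- 1L - label
    list(chain = ch,
         cdr3_start = ch$regions$start[["CDR3"]],
         cdr3_end = ch$regions$end[["CDR3"]],
         label = label, clean_label = clean)
  })
}
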