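#' Configuration of the synthetic superfamily generator
#'
#' Defaults emulate a small remote-homology benchmark: superfamilies whose
#' families descend from a common ancestor, with within-family members
#' separated by few substitutions (0.05 expected substitutions per site)
#' and families separated by many (0.5 per site) — the within/between
#' contrast that the recognition-rate statistics assume.
#'
#' @param seed Integer RNG seed; generation is bit-reproducible given it.
#' @param n_superfamilies,families_per_sf,proteins_per_family Counts
#'   (defaults 10, 3, 4).
#' @param length_range Ancestor length range in residues (default 60-120,
#'   inside the method's 50-500 working range).
#' @param within_family_subs Expected substitutions per site between a
#'   family founder and a member (default 0.05).
#' @param between_family_subs Expected substitutions per site between the
#'   superfamily ancestor and a family founder (default 0.5); must exceed
#'   `within_family_subs`.
#' @param pssm_concentration Weight of the one-hot component in pseudo-PSSM
#'   rows (`conc * one-hot + (1-conc) * uniform`; default 0.9).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_superfamilies = 10L,
                             families_per_sf = 3L,
                             proteins_per_family = 4L,
                             length_range = c(60L, 120L),
                             within_family_subs = 0.05,
                             between_family_subs = 0.5,
                             pssm_concentration = 0.9) {
  stopifnot(n_superfamilies >= 1L, families_per_sf >= 1L,
            proteins_per_family >= 1L,
            length(length_range) == 2L,
            length_range[1] >= 10L, length_range[2] <= 1000L,
            length_range[1] <= length_range[2],
            within_family_subs >= 0, within_family_subs <= 1,
            between_family_subs <= 1,
            pssm_concentration >= 0, pssm_concentration <= 1)
  if (between_family_subs <= within_family_subs) {
    stop("between_family_subs must exceed within_family_subs", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_superfamilies = as.integer(n_superfamilies),
                 families_per_sf = as.integer(families_per_sf),
                 proteins_per_family = as.integer(proteins_per_family),
                 length_range = as.integer(length_range),
                 within_family_subs = within_family_subs,
                 between_family_subs = between_family_subs,
                 pssm_concentration = pssm_concentration),
            class = "synthetic_config")
}

# run local RNG state; restores the caller's stream afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

mutate_sequence <- function(letters, rate) {
  hit <- runif(length(letters)) < rate
  if (any(hit)) {
    letters[hit] <- vapply(letters[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  letters
}

# drift structure labels along with the sequence: each site relabels
# with the same per-site probability as the substitution rate
mutate_ss <- function(ss, rate) {
  hit <- runif(length(ss)) < rate
  if (any(hit)) {
    ss[hit] <- vapply(ss[hit], function(s) {
      sample(setdiff(SS_ALPHABET, s), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  ss
}

mutate_rasa <- function(rasa, rate) {
  hit <- runif(length(rasa)) < rate
  if (any(hit)) rasa[hit] <- draw_rasa(sum(hit))
  rasa
}

# uniform rASA, rounded so a written fixture round-trips exactly and never
# sits on the buried/exposed threshold
draw_rasa <- function(n) {
  r <- round(runif(n), 6)
  r[r == RASA_BURIED_THRESHOLD] <- RASA_BURIED_THRESHOLD + 1e-6
  r
}

# secondary-structure string as geometric runs (mean run length 5)
draw_ss_runs <- function(L, mean_run = 5) {
  out <- character(0)
  while (length(out) < L) {
    state <- sample(SS_ALPHABET, 1L)
    len <- 1L + rgeom(1L, 1 / mean_run)
    out <- c(out, rep(state, len))
  }
  out[seq_len(L)]
}

pseudo_pssm <- function(letters, concentration) {
  L <- length(letters)
  m <- matrix((1 - concentration) / 20, L, 20L)
  m[cbind(seq_len(L), aa_index(letters))] <-
    m[cbind(seq_len(L), aa_index(letters))] + concentration
  colnames(m) <- AA_ALPHABET
  m
}

#' Generate a synthetic superfamily benchmark
#'
#' Per superfamily: an ancestor sequence is drawn uniformly over the
#' amino-acid alphabet; each family founder derives from it by i.i.d.
#' per-site substitutions at rate `between_family_subs` (target uniform
#' over the 19 alternatives), and each family member derives from its
#' founder at rate `within_family_subs`. Secondary-structure labels are
#' drawn as geometric runs at the ancestor and relabel along each
#' derivation at the same per-site rate; rASA values are uniform on
#' `[0, 1]`, redrawn at the same rate, and thresholded at 20% into B/E.
#' Pseudo-PSSM rows mix a one-hot on the observed residue with the
#' uniform distribution. The generating ("truth") tree of each
#' superfamily groups members under their family.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `records` (list of [protein_record()]), `labels`
#'   (tibble id/family/superfamily), `truth` (named list of `phylo`
#'   trees, one per superfamily), `rasa` (named list of per-site rASA
#'   vectors, for fixture writing), `founders` (named list of family
#'   founder sequences) and `config`.
#' @export
make_superfamily <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    records <- list()
    rasa_all <- list()
    labels <- list()
    truth <- list()
    founders <- list()
    for (s in seq_len(cfg$n_superfamilies)) {
      sf_id <- sprintf("sf%02d", s)
      L <- cfg$length_range[1] +
        sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L, 1L) - 1L
      anc_seq <- sample(AA_ALPHABET, L, replace = TRUE)
      anc_ss <- draw_ss_runs(L)
      anc_rasa <- draw_rasa(L)

      fam_frags <- character(cfg$families_per_sf)
      for (f in seq_len(cfg$families_per_sf)) {
        fam_id <- sprintf("%s_f%02d", sf_id, f)
        fo_seq <- mutate_sequence(anc_seq, cfg$between_family_subs)
        fo_ss <- mutate_ss(anc_ss, cfg$between_family_subs)
        fo_rasa <- mutate_rasa(anc_rasa, cfg$between_family_subs)
        founders[[fam_id]] <- paste(fo_seq, collapse = "")

        tip_frags <- character(cfg$proteins_per_family)
        for (p in seq_len(cfg$proteins_per_family)) {
          pid <- sprintf("%s_p%02d", fam_id, p)
          sq <- mutate_sequence(fo_seq, cfg$within_family_subs)
          ss <- mutate_ss(fo_ss, cfg$within_family_subs)
          ra <- mutate_rasa(fo_rasa, cfg$within_family_subs)
          rec <- suppressWarnings(protein_record(
            pid, paste(sq, collapse = ""),
            aa_probs = pseudo_pssm(sq, cfg$pssm_concentration),
            ss = paste(ss, collapse = ""),
            acc = paste(ifelse(ra < RASA_BURIED_THRESHOLD, "B", "E"),
                        collapse = "")
          ))
          records[[pid]] <- rec
          rasa_all[[pid]] <- ra
          labels[[pid]] <- tibble::tibble(id = pid, family = fam_id,
                                          superfamily = sf_id)
          tip_frags[p] <- sprintf("%s:%g", pid, cfg$within_family_subs)
        }
        fam_frags[f] <- sprintf("(%s):%g", paste(tip_frags, collapse = ","),
                                cfg$between_family_subs)
      }
      truth[[sf_id]] <- ape::read.tree(
        text = paste0("(", paste(fam_frags, collapse = ","), ");"))
    }
    list(records = unname(records), labels = dplyr::bind_rows(labels),
         truth = truth, rasa = rasa_all, founders = founders, config = cfg)
  })
}

#' Random additive distance matrix with its generating tree
#'
#' Draws a random unrooted binary tree with branch lengths uniform on
#' `[0.1, 1]` and returns it with its exact leaf-to-leaf path-length
#' matrix — an additive matrix on which a consistent distance method must
#' recover the tree.
#'
#' @param n_leaves Number of leaves, at least 3.
#' @param seed Integer RNG seed.
#' @return List with `tree` (`phylo`) and `dm` (labelled matrix).
#' @export
make_additive_matrix <- function(n_leaves, seed = 1L) {
  stopifnot(n_leaves >= 3L)
  with_local_seed(seed, {
    tree <- ape::rtree(n_leaves, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    dm <- ape::cophenetic.phylo(tree)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    list(tree = tree, dm = validate_distance_matrix(dm))
  })
}

#' Write a synthetic benchmark as an on-disk fixture directory
#'
#' Emits the files the file-based pipeline consumes: `sequences.fasta`,
#' one `<id>.pssm` (PSI-BLAST ASCII dialect) and `<id>.ss.tsv` per record,
#' `labels.tsv`, and one `truth_<superfamily>.nwk` per generating tree.
#'
#' @param sim Output of [make_superfamily()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture_dir <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- vapply(sim$records, `[[`, character(1), "sequence")
  ids <- vapply(sim$records, `[[`, character(1), "id")
  writeLines(paste0(">", ids, "\n", seqs), file.path(dir, "sequences.fasta"))
  for (rec in sim$records) {
    write_pssm(rec$aa_probs, rec$sequence,
               file.path(dir, paste0(rec$id, ".pssm")))
    write_local_structure(rec$ss, sim$rasa[[rec$id]], rec$sequence,
                          file.path(dir, paste0(rec$id, ".ss.tsv")))
  }
  utils::write.table(sim$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sf in names(sim$truth)) {
    write_newick(sim$truth[[sf]], file.path(dir, paste0("truth_", sf, ".nwk")))
  }
  invisible(dir)
}
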