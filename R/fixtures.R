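#' Configuration for the synthetic structure-activity generator
#'
#' The generator emulates the shape of a curated carcinogenicity dataset
#' — SMILES-like strings, a numeric descriptor table and labels/doses —
#' with a planted, learnable rule: activity is driven by a structural
#' motif (default the nitro group written as `N(=O)=O`, a classic
#' structural alert for carcinogenicity), and the first descriptor is a
#' noisy reporter of that motif. Every stage of the pipeline is therefore
#' testable without any external dataset.
#'
#' @param n number of chemicals.
#' @param seed integer seed; the whole fixture is a deterministic
#'   function of `(config, seed)`.
#' @param motif planted substring over the 94-character vocabulary.
#' @param motif_prevalence fraction of chemicals carrying the motif.
#' @param label_noise epsilon in `[0, 0.5)`: probability that a binary
#'   label is flipped away from the motif rule.
#' @param n_descriptors number of descriptor columns (>= 2).
#' @param effect_size beta: weight of the motif count in the ternary
#'   score and the regression mean.
#' @param regression_noise sigma of the Gaussian noise on pTD50.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n = 2000L, seed = 1L, motif = "N(=O)=O",
                           motif_prevalence = 0.5, label_noise = 0.1,
                           n_descriptors = 16L, effect_size = 1,
                           regression_noise = 0.5) {
  stopifnot(label_noise >= 0, label_noise < 0.5, n_descriptors >= 2L,
            regression_noise >= 0, motif_prevalence >= 0,
            motif_prevalence <= 1, nchar(motif) >= 1L)
  structure(list(n = as.integer(n), seed = as.integer(seed), motif = motif,
                 motif_prevalence = motif_prevalence,
                 label_noise = label_noise,
                 n_descriptors = as.integer(n_descriptors),
                 effect_size = effect_size,
                 regression_noise = regression_noise),
            class = "fixture_config")
}

# SMILES-like token alphabet; "Cl" is deliberately a two-character token
# so that fixtures exercise the character-level (not token-level) codec.
.fixture_tokens <- c("C", "c", "N", "O", "=", "#", "(", ")", "1", "2", "Cl")

#' Generate synthetic SMILES-like strings
#'
#' Strings of 5-120 characters over a small SMILES-like alphabet; an
#' exact `round(motif_prevalence * n)` of them contain the planted motif
#' (inserted at a random position), and none of the others do. All
#' characters lie in ASCII 33..126, so every output encodes without error.
#'
#' @param cfg a [fixture_config()].
#' @return character vector of length `cfg$n` with attribute `has_motif`
#'   (logical vector).
#' @export
generate_smiles <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  n_motif <- round(cfg$motif_prevalence * n)
  motif_rows <- if (n_motif > 0) sample.int(n, n_motif) else integer(0)
  max_base <- 120L - nchar(cfg$motif)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(5:max_base, 1L)
      s <- paste(sample(.fixture_tokens, len, replace = TRUE),
                 collapse = "")
      s <- substr(s, 1L, max_base)
      if (!grepl(cfg$motif, s, fixed = TRUE)) break  # accidental motif: redraw
    }
    if (i %in% motif_rows) {
      at <- sample.int(nchar(s) + 1L, 1L)
      s <- paste0(substr(s, 1L, at - 1L), cfg$motif,
                  substr(s, at, nchar(s)))
    }
    out[i] <- s
  }
  attr(out, "has_motif") <- seq_len(n) %in% motif_rows
  out
}

.count_motif <- function(smiles, motif) {
  vapply(gregexpr(motif, smiles, fixed = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
}

#' Generate a full synthetic dataset for one task
#'
#' Builds SMILES via [generate_smiles()], then a descriptor table whose
#' first column `D001` is the motif count plus Gaussian noise (sd 0.25)
#' and whose remaining columns are independent standard normals, and task
#' targets: binary label = motif indicator XOR Bernoulli(label_noise);
#' ternary label = the score `beta * count + D001 + N(0,1)` cut at its
#' empirical tertiles; regression pTD50 =
#' `beta * count + 0.5 * D001 + N(0, sigma)`.
#'
#' @param cfg a [fixture_config()].
#' @param task "binary", "multiclass" or "regression".
#' @return list with `records` (data.frame: id, smiles, motif_count and
#'   the task's target column `binary_label` / `multiclass_label` /
#'   `ptd50`) and `descriptors` (data.frame keyed by id).
#' @export
generate_dataset <- function(cfg, task = c("binary", "multiclass",
                                           "regression")) {
  task <- match.arg(task)
  stopifnot(inherits(cfg, "fixture_config"))
  smiles <- generate_smiles(cfg)
  n <- cfg$n
  count <- .count_motif(smiles, cfg$motif)
  set.seed(cfg$seed + 1L)
  # d1 is a low-noise reporter of the motif (sd 0.25), so that a stump on
  # d1 alone can recover the noiseless rule; the remaining descriptors are
  # pure standard-normal distractors
  d1 <- count + stats::rnorm(n, sd = 0.25)
  desc <- matrix(stats::rnorm(n * (cfg$n_descriptors - 1L)), n)
  desc <- cbind(d1, desc)
  colnames(desc) <- sprintf("D%03d", seq_len(cfg$n_descriptors))
  ids <- sprintf("CHEM%05d", seq_len(n))
  desc <- as.data.frame(desc)
  rownames(desc) <- ids
  records <- data.frame(id = ids, smiles = as.character(smiles),
                        motif_count = count, stringsAsFactors = FALSE)
  beta <- cfg$effect_size
  if (task == "binary") {
    flip <- stats::runif(n) < cfg$label_noise
    records$binary_label <- as.integer(xor(count > 0, flip))
  } else if (task == "multiclass") {
    score <- beta * count + d1 + stats::rnorm(n)
    cuts <- stats::quantile(score, c(1 / 3, 2 / 3))
    records$multiclass_label <- as.integer(score > cuts[1]) +
      as.integer(score > cuts[2])
  } else {
    records$ptd50 <- beta * count + 0.5 * d1 +
      stats::rnorm(n, sd = cfg$regression_noise)
  }
  list(records = records, descriptors = desc)
}

#' Twenty real hand-checked SMILES
#'
#' A small bundled table of real chemicals (common carcinogens and
#' innocuous reference compounds) for smoke-testing the codec and any
#' external descriptor provider. These are genuine structures, unlike the
#' synthetic strings from [generate_smiles()].
#'
#' @return data.frame with columns `name` and `smiles`.
#' @export
real_smiles_sample <- function() {
  path <- system.file("extdata", "real_smiles_sample.csv",
                      package = "hnncarc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
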