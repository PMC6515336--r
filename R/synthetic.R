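# Synthetic labeled datasets. The generator emulates a post-descriptor
# modeling table: two-class Gaussian feature blocks with a controllable
# between-class separation, plus verifiably injected redundant and
# near-constant columns and planted label noise. A Gaussian class-
# conditional model keeps the Bayes error available in closed form as a
# cross-check. A companion hand-picked SMILES fixture exercises every
# standardization branch.

#' Specification for a synthetic labeled descriptor dataset
#'
#' @param n number of compounds.
#' @param n_features total feature count (informative + redundant +
#'   near-constant).
#' @param class_balance fraction of positives in `(0, 1)`.
#' @param signal between-class mean separation of every informative feature,
#'   in within-class SD units (standardized mean difference). 0 = no signal.
#' @param n_redundant features duplicated from informative ones with
#'   `|r| > 0.95` (small additive noise).
#' @param n_near_constant features whose modal value frequency is ~0.97.
#' @param label_noise fraction of labels flipped after generation, in
#'   `[0, 1)`; flipped ids are recorded in the truth record.
#' @param seed RNG seed; identical seeds give byte-identical datasets.
#' @return validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 1254, n_features = 55, class_balance = 0.5,
                           signal = 1, n_redundant = 0, n_near_constant = 0,
                           label_noise = 0, seed = 1) {
  spec <- list(n = n, n_features = n_features, class_balance = class_balance,
               signal = signal, n_redundant = n_redundant,
               n_near_constant = n_near_constant, label_noise = label_noise,
               seed = seed)
  check <- function(ok, field, msg) if (!ok) stop("invalid spec field '", field, "': ", msg)
  check(is.numeric(n) && n >= 4 && n == round(n), "n", "need integer >= 4")
  check(is.numeric(n_features) && n_features >= 1 && n_features == round(n_features),
        "n_features", "need positive integer")
  check(is.numeric(class_balance) && class_balance > 0 && class_balance < 1,
        "class_balance", "need value in (0, 1)")
  check(is.numeric(signal) && signal >= 0, "signal", "need value >= 0")
  check(n_redundant >= 0 && n_redundant == round(n_redundant),
        "n_redundant", "need non-negative integer")
  check(n_near_constant >= 0 && n_near_constant == round(n_near_constant),
        "n_near_constant", "need non-negative integer")
  check(n_redundant + n_near_constant < n_features, "n_features",
        "need at least one informative feature")
  check(is.numeric(label_noise) && label_noise >= 0 && label_noise < 1,
        "label_noise", "need value in [0, 1)")
  check(is.numeric(seed) && seed == round(seed), "seed", "need integer")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic labeled descriptor dataset
#'
#' Informative features are unit-variance Gaussians whose class means differ
#' by `signal` SDs. Redundant features copy informative ones plus N(0, 0.08)
#' noise (population correlation ~0.997). Near-constant features take their
#' modal value with frequency ~0.97. Label noise flips a recorded random
#' subset of labels.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (n x n_features, rownames = compound ids),
#'   `labels` (character), `truth` (informative/redundant/near-constant
#'   feature names, redundancy sources, flipped ids, clean labels) and
#'   `spec`.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  n_inf <- spec$n_features - spec$n_redundant - spec$n_near_constant
  ids <- sprintf("cmpd%04d", seq_len(n))
  feat <- sprintf("F%03d", seq_len(spec$n_features))
  inf_names <- feat[seq_len(n_inf)]
  red_names <- if (spec$n_redundant) feat[n_inf + seq_len(spec$n_redundant)] else character(0)
  nc_names <- if (spec$n_near_constant) feat[n_inf + spec$n_redundant +
                                               seq_len(spec$n_near_constant)] else character(0)
  out <- with_seed(spec$seed, {
    n_pos <- round(spec$class_balance * n)
    labels <- sample(c(rep("positive", n_pos), rep("negative", n - n_pos)))
    x <- matrix(stats::rnorm(n * n_inf), n, n_inf)
    x <- x + (labels == "positive") * spec$signal
    red_src <- if (spec$n_redundant) sample(seq_len(n_inf), spec$n_redundant,
                                            replace = TRUE) else integer(0)
    xr <- if (spec$n_redundant) {
      x[, red_src, drop = FALSE] + matrix(stats::rnorm(n * spec$n_redundant, sd = 0.08),
                                          n, spec$n_redundant)
    } else matrix(0, n, 0)
    xc <- if (spec$n_near_constant) {
      vapply(seq_len(spec$n_near_constant), function(j) {
        v <- rep(0, n)
        hot <- sample.int(n, max(1, round(0.03 * n)))
        v[hot] <- 1
        v
      }, numeric(n))
    } else matrix(0, n, 0)
    clean <- labels
    flipped <- character(0)
    n_flip <- round(spec$label_noise * n)
    if (n_flip > 0) {
      fi <- sample.int(n, n_flip)
      labels[fi] <- ifelse(labels[fi] == "positive", "negative", "positive")
      flipped <- ids[fi]
    }
    list(x = cbind(x, xr, xc), labels = labels, clean = clean,
         flipped = flipped, red_src = red_src)
  })
  mat <- out$x
  dimnames(mat) <- list(ids, feat)
  list(
    matrix = mat,
    labels = out$labels,
    truth = list(
      informative = inf_names,
      redundant = red_names,
      redundant_source = stats::setNames(inf_names[out$red_src], red_names),
      near_constant = nc_names,
      flipped_ids = out$flipped,
      clean_labels = stats::setNames(out$clean, ids)
    ),
    spec = spec
  )
}

#' Hand-picked SMILES fixture spanning every standardization branch
#'
#' Roughly thirty structures: well-behaved drugs, salt and solvate forms,
#' charged species needing neutralization, a stereoisomer pair that must
#' collapse to one key, metal-/rare-atom compounds, true mixtures, inorganic
#' species, carbon-count and molecular-weight boundary cases, and
#' unparsable strings. `expected_status` records the truth table the full
#' standardization pass must reproduce.
#'
#' @return compound record data.frame with extra columns `expected_status`
#'   and `note`.
#' @export
toy_smiles_fixture <- function() {
  e <- function(id, smi, lab, status, note)
    data.frame(compound_id = id, smiles = smi, label = lab,
               expected_status = status, note = note, stringsAsFactors = FALSE)
  big_ok <- paste(rep("C", 64), collapse = "")    # C64 alkane, MW ~899.7
  big_no <- paste(rep("C", 65), collapse = "")    # C65 alkane, MW ~913.8
  tab <- rbind(
    e("aspirin", "CC(=O)Oc1ccccc1C(=O)O", "positive", "active", "well-behaved drug"),
    e("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "negative", "active", "well-behaved drug"),
    e("ibuprofen", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "positive", "active", "well-behaved drug"),
    e("paracetamol", "CC(=O)Nc1ccc(O)cc1", "positive", "active", "well-behaved drug"),
    e("diazepam", "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21", "positive", "active", "well-behaved drug"),
    e("naproxen", "COc1ccc2cc(C(C)C(=O)O)ccc2c1", "positive", "active", "well-behaved drug"),
    e("nicotine_L", "CN1CCC[C@H]1c1cccnc1", "negative", "active", "stereo pair member"),
    e("nicotine_D", "CN1CCC[C@@H]1c1cccnc1", "negative", "active", "stereo pair member"),
    e("valine_L", "CC(C)[C@@H](N)C(=O)O", "negative", "active", "stereo pair member"),
    e("valine_D", "CC(C)[C@H](N)C(=O)O", "negative", "active", "stereo pair member"),
    e("na_benzoate", "[Na+].[O-]C(=O)c1ccccc1", "negative", "active", "salt -> benzoic acid"),
    e("fluoxetine_hcl", "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1.Cl", "positive", "active", "HCl salt"),
    e("amine_hcl", "CC(C)CC(C)[NH3+].[Cl-]", "negative", "active", "protonated amine salt"),
    e("paracetamol_hydrate", "CC(=O)Nc1ccc(O)cc1.O", "positive", "active", "water stripped; same key as paracetamol"),
    e("pyridinium_cl", "c1cc[nH+]cc1.[Cl-]", "negative", "active", "aromatic cation neutralized"),
    e("gaba_anion", "NCCCC(=O)[O-]", "negative", "active", "carboxylate neutralized"),
    e("tms", "C[Si](C)(C)C", "negative", "active", "silicon is whitelisted"),
    e("se_met", "C[Se]CCC(N)C(=O)O", "negative", "active", "selenium is whitelisted"),
    e("butane", "CCCC", "negative", "active", "carbon-count boundary: exactly 4 kept"),
    e("big_c64", big_ok, "negative", "active", "MW boundary: ~899.7 kept"),
    e("phenylmercury", "CC[Hg]c1ccccc1", "positive", "rejected_structure", "metal atom"),
    e("tetraethyltin", "CC[Sn](CC)CC", "positive", "rejected_structure", "metal atom"),
    e("cisplatin", "N.N.Cl[Pt]Cl", "positive", "rejected_structure", "inorganic/metal complex"),
    e("saline", "[Na+].[Cl-]", "negative", "rejected_structure", "inorganic salt"),
    e("water", "O", "negative", "rejected_structure", "inorganic"),
    e("oct_mixture", "CCCCCCCCO.CCCCCCCC(=O)O", "negative", "rejected_structure", "true two-component mixture"),
    e("bad_smiles", "C1CC", "negative", "rejected_structure", "unclosed ring, unparsable"),
    e("garbage", "QX%zz", "negative", "rejected_structure", "unparsable string"),
    e("propane", "CCC", "negative", "rejected_size", "3 carbons"),
    e("methanol", "CO", "negative", "rejected_size", "1 carbon"),
    e("big_c65", big_no, "negative", "rejected_size", "MW ~913.8 > 900")
  )
  rec <- compound_records(tab$compound_id, tab$smiles, tab$label,
                          source_name = "toy_fixture", source_tier = "tier2")
  rec$expected_status <- tab$expected_status
  rec$note <- tab$note
  rec
}
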