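#' Configuration for simulating structured biallelic genotypes
#'
#' Describes a panel of mostly inbred lines drawn from a small number of
#' subpopulations (default 5, the number of groups typically resolved by
#' PCA + k-means in European wheat panels), with markers laid out on the 21
#' bread-wheat chromosomes, planted missingness, and an optional causal
#' region whose minor alleles shift one trait.
#'
#' @param n_markers total marker count.
#' @param n_groups number of subpopulations (>= 1).
#' @param fst Wright's fixation index controlling group differentiation of
#'   allele frequencies (Balding-Nichols model).
#' @param missing_rate fraction of dosages set missing at random, in \[0, 1).
#' @param maf_range range of ancestral allele frequencies (uniform draw).
#' @param chromosomes chromosome names for the marker map.
#' @param chrom_length_mbp map length per chromosome in Mbp.
#' @param causal_region `NULL` or a list with elements `chrom`, `start`,
#'   `end` (Mbp), `n_causal` (markers planted inside), `effect` (trait shift
#'   per minor allele, trait units) and `trait` (panel trait name).
#' @param hybrid_fraction fraction of cultivars simulated as hybrids
#'   (heterozygous calls allowed); pure lines are coded 0/2 only.
#' @param seed integer root seed.
#' @return object of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_markers = 2000L, n_groups = 5L, fst = 0.15,
                            missing_rate = 0.02,
                            maf_range = c(0.1, 0.9),
                            chromosomes = paste0(rep(1:7, each = 3),
                                                 c("A", "B", "D")),
                            chrom_length_mbp = 800,
                            causal_region = list(chrom = "6A", start = 400,
                                                 end = 442, n_causal = 5L,
                                                 effect = -8, trait = "gcd"),
                            hybrid_fraction = 0.03, seed = 1L) {
  n_markers <- check_count(n_markers, "n_markers")
  n_groups <- check_count(n_groups, "n_groups")
  check_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  check_number(fst, "fst", 1e-6, 0.999)
  check_number(hybrid_fraction, "hybrid_fraction", 0, 1)
  if (!is.null(causal_region)) {
    need <- c("chrom", "start", "end", "n_causal", "effect", "trait")
    if (!all(need %in% names(causal_region))) {
      stop_sg("causal_region must name %s", paste(need, collapse = ", "))
    }
    if (!causal_region$chrom %in% chromosomes) {
      stop_sg("causal region chromosome '%s' not on the marker map",
              causal_region$chrom)
    }
  }
  structure(list(n_markers = n_markers, n_groups = n_groups, fst = fst,
                 missing_rate = missing_rate, maf_range = maf_range,
                 chromosomes = chromosomes,
                 chrom_length_mbp = chrom_length_mbp,
                 causal_region = causal_region,
                 hybrid_fraction = hybrid_fraction,
                 seed = as.integer(seed)),
            class = "geno_sim_config")
}

#' Construct a genotype matrix object
#'
#' @param dosage numeric matrix, markers in rows, cultivars in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param map `data.frame` with columns `marker`, `chrom`, `pos_mbp`; must
#'   cover every row of `dosage` exactly once.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop_sg("dosages must be 0, 1, 2 or NA")
  if (!all(c("marker", "chrom", "pos_mbp") %in% names(map))) {
    stop_sg("map must have columns marker, chrom, pos_mbp")
  }
  if (anyDuplicated(map$marker) || !setequal(map$marker, rownames(dosage))) {
    stop_sg("map must cover every marker exactly once")
  }
  map <- map[match(rownames(dosage), map$marker), , drop = FALSE]
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d cultivars, %d chromosome(s), %.1f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Simulate structured biallelic genotypes for a cultivar panel
#'
#' Draws ancestral allele frequencies per marker, differentiates them across
#' subpopulations under the Balding-Nichols model (`Beta(p(1-F)/F,
#' (1-p)(1-F)/F)` with `F` = `fst`), and samples dosages per cultivar from
#' its group's frequency: pure lines are homozygous (0/2, one Bernoulli
#' draw), hybrids carry two draws (0/1/2). Missingness is completely at
#' random. If a causal region is configured, `n_causal` markers inside it
#' are flagged and a per-cultivar genetic value `effect x minor-allele
#' count` is recorded (apply it to a trait with [apply_causal_effect()]).
#'
#' @param config a [geno_sim_config()].
#' @param cultivars character vector of cultivar ids, or a
#'   [simulate_panel()] table (ids are taken from it).
#' @return a [geno_matrix()] with attribute `"truth"` (group assignments,
#'   causal marker ids, per-cultivar causal values).
#' @export
simulate_genotypes <- function(config, cultivars) {
  stopifnot(inherits(config, "geno_sim_config"))
  if (inherits(cultivars, "phenotype_table")) {
    cultivars <- unique(cultivars$cultivar)
  }
  n_ind <- length(cultivars)
  if (n_ind < 2L) stop_sg("need at least 2 cultivars")
  cfg <- config
  m <- cfg$n_markers

  map <- with_stream(cfg$seed, "map", {
    chrom <- sort(sample(cfg$chromosomes, m, replace = TRUE))
    pos <- runif(m, 0, cfg$chrom_length_mbp)
    ord <- order(chrom, pos)
    data.frame(marker = sprintf("mk%05d", seq_len(m)),
               chrom = chrom[ord], pos_mbp = pos[ord],
               stringsAsFactors = FALSE)
  })

  groups <- with_stream(cfg$seed, "groups",
                        sample(seq_len(cfg$n_groups), n_ind, replace = TRUE))
  is_hybrid <- with_stream(cfg$seed, "hybrids",
                           runif(n_ind) < cfg$hybrid_fraction)

  p_anc <- with_stream(cfg$seed, "ancestral_freq",
                       runif(m, cfg$maf_range[1], cfg$maf_range[2]))
  pg <- with_stream(cfg$seed, "group_freq", {
    if (cfg$n_groups == 1L) {
      matrix(p_anc, m, 1)
    } else {
      a <- p_anc * (1 - cfg$fst) / cfg$fst
      b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
      vapply(seq_len(cfg$n_groups), function(g) rbeta(m, a, b), numeric(m))
    }
  })
  pg <- pmin(pmax(pg, 0.01), 0.99)

  dosage <- with_stream(cfg$seed, "dosage", {
    d <- matrix(0L, m, n_ind)
    for (j in seq_len(n_ind)) {
      p <- pg[, groups[j]]
      d[, j] <- if (is_hybrid[j]) {
        rbinom(m, 2L, p)
      } else {
        2L * rbinom(m, 1L, p)
      }
    }
    d
  })
  if (cfg$missing_rate > 0) {
    dosage <- with_stream(cfg$seed, "missing", {
      d <- dosage
      d[runif(length(d)) < cfg$missing_rate] <- NA
      d
    })
  }
  rownames(dosage) <- map$marker
  colnames(dosage) <- cultivars

  truth <- list(groups = setNames(groups, cultivars),
                causal_markers = character(0),
                causal_values = setNames(rep(0, n_ind), cultivars),
                effect = 0, trait = NULL)
  cr <- cfg$causal_region
  if (!is.null(cr)) {
    inside <- which(map$chrom == cr$chrom &
                    map$pos_mbp >= cr$start & map$pos_mbp <= cr$end)
    if (length(inside) == 0L) {
      stop_sg("causal region %s:%g-%g Mbp contains no markers",
              cr$chrom, cr$start, cr$end)
    }
    picked <- with_stream(cfg$seed, "causal",
                          sample(inside, min(cr$n_causal, length(inside))))
    picked <- sort(picked)
    # burden of minor alleles over the causal markers (missing -> 0)
    sub <- dosage[picked, , drop = FALSE]
    minor <- minor_allele_dosage(sub)
    burden <- colSums(minor, na.rm = TRUE)
    truth$causal_markers <- map$marker[picked]
    truth$causal_values <- setNames(cr$effect * burden, cultivars)
    truth$effect <- cr$effect
    truth$trait <- cr$trait
  }
  g <- geno_matrix(dosage, map)
  attr(g, "truth") <- truth
  g
}

#' Recode a dosage matrix to minor-allele dosage
#' @param dosage markers x cultivars matrix of 0/1/2/NA.
#' @return matrix of minor-allele counts per cultivar.
#' @keywords internal
minor_allele_dosage <- function(dosage) {
  freq <- rowMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  dosage[flip, ] <- 2 - dosage[flip, , drop = FALSE]
  dosage
}

#' Add a planted causal genetic value to one trait of a panel
#'
#' @param panel a [simulate_panel()] table.
#' @param geno a [simulate_genotypes()] result with a causal region.
#' @param trait trait to shift; defaults to the trait named in the causal
#'   configuration.
#' @return the panel with shifted `value`s (truth attribute updated).
#' @export
apply_causal_effect <- function(panel, geno, trait = NULL) {
  truth_g <- attr(geno, "truth")
  if (is.null(truth_g) || length(truth_g$causal_markers) == 0L) {
    stop_sg("genotypes carry no causal region")
  }
  trait <- trait %||% truth_g$trait
  if (!trait %in% panel$trait) stop_sg("trait '%s' not in panel", trait)
  shift <- truth_g$causal_values[panel$cultivar]
  sel <- panel$trait == trait
  panel$value[sel] <- panel$value[sel] + shift[sel]
  tr <- attr(panel, "truth")
  if (!is.null(tr)) {
    cv <- truth_g$causal_values[names(tr$traits[[trait]]$cultivar_effects)]
    tr$traits[[trait]]$cultivar_effects <-
      tr$traits[[trait]]$cultivar_effects + cv
    tr$traits[[trait]]$causal_markers <- truth_g$causal_markers
    attr(panel, "truth") <- tr
  }
  panel
}
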