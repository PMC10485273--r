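#' Construct a tetraploid (or diploid) parent genotype
#'
#' Builds the simulator's ground-truth parent: one allele-label vector per
#' homologue over the marker map. By default every homologue carries its own
#' label (homologue h carries allele h at every marker), so allele labels
#' coincide with homologue identity and the allele linked to the dominant
#' determinant is label 1 -- the convention used when scoring polyhaploids,
#' where the dominant-linked allele is designated allele 1.
#'
#' @param map A `marker_map`.
#' @param n_homologues 4 for a tetraploid parent (the default), 2 for a
#'   diploid (e.g. a polyhaploid producing haploid gametes).
#' @param selection_locus Marker name of the gametophytically selected locus;
#'   defaults to the marker at `phys_kb == 0` if present, else the first
#'   marker.
#' @param dominant_homologue Index of the homologue carrying the dominant
#'   determinant (simplex by default: exactly one).
#' @return A `parent_genotype`: list with elements `map`, `homologues`
#'   (integer matrix, homologue x marker, `NA` marking deleted segments),
#'   `selection_locus`, `dominant_homologue` and `dominant_allele`.
#' @export
#' @examples
#' m <- marker_map("PAR", 0, 0)
#' make_parent(m)
make_parent <- function(map, n_homologues = 4L, selection_locus = NULL,
                        dominant_homologue = 1L) {
  validate_marker_map(map)
  n_homologues <- as.integer(n_homologues)
  if (!n_homologues %in% c(2L, 4L))
    .stop_ctx("n_homologues must be 2 or 4")
  if (is.null(selection_locus)) {
    hit <- which(map$phys_kb == 0)
    selection_locus <- if (length(hit)) map$name[hit[1L]] else map$name[1L]
  }
  if (!selection_locus %in% map$name)
    .stop_ctx("selection_locus '", selection_locus, "' not in map")
  if (dominant_homologue < 1L || dominant_homologue > n_homologues)
    .stop_ctx("dominant_homologue out of range")
  hom <- matrix(rep(seq_len(n_homologues), times = nrow(map)),
                nrow = n_homologues,
                dimnames = list(NULL, map$name))
  parent <- list(
    map = map,
    homologues = hom,
    selection_locus = selection_locus,
    dominant_homologue = as.integer(dominant_homologue),
    dominant_allele = unname(hom[dominant_homologue,
                                 match(selection_locus, map$name)])
  )
  class(parent) <- "parent_genotype"
  parent
}

#' @export
print.parent_genotype <- function(x, ...) {
  cat(sprintf(
    "Parent genotype: %d homologues x %d markers; selection locus '%s' (dominant allele %d on homologue %d)\n",
    nrow(x$homologues), ncol(x$homologues), x$selection_locus,
    x$dominant_allele, x$dominant_homologue))
  if (any(is.na(x$homologues)))
    cat(sprintf("  %d deleted marker positions\n", sum(is.na(x$homologues))))
  invisible(x)
}

#' Derive a deletion mutant from a parent genotype
#'
#' Marks all markers whose physical coordinate falls inside a half-open
#' interval `[start, end)` (signed kb) as absent on one homologue, emulating
#' radiation-induced deletion mutants. An empty interval returns the parent
#' unchanged.
#'
#' @param parent A `parent_genotype`.
#' @param homologue_index Homologue carrying the deletion.
#' @param interval_kb Numeric length-2 half-open interval `[start, end)` in
#'   signed kb.
#' @return The modified `parent_genotype` (deleted positions become `NA`).
#' @export
make_deletion_mutant <- function(parent, homologue_index, interval_kb) {
  stopifnot(inherits(parent, "parent_genotype"))
  h <- as.integer(homologue_index)
  if (h < 1L || h > nrow(parent$homologues))
    .stop_ctx("homologue index out of range")
  if (length(interval_kb) != 2L || any(!is.finite(interval_kb)))
    .stop_ctx("interval_kb must be two finite numbers [start, end)")
  lo <- min(interval_kb); hi <- max(interval_kb)
  span <- range(parent$map$phys_kb)
  if (lo == hi) return(parent)
  if (hi < span[1L] || lo > span[2L])
    .stop_ctx("deletion interval lies outside the map's physical span")
  inside <- parent$map$phys_kb >= lo & parent$map$phys_kb < hi
  parent$homologues[h, inside] <- NA_integer_
  sel <- match(parent$selection_locus, parent$map$name)
  parent$dominant_allele <- unname(
    parent$homologues[parent$dominant_homologue, sel])
  parent
}

#' Gametophytic selection model
#'
#' Describes which meiotic products survive to be observed as polyhaploids.
#' `require_dominant` keeps only gametes carrying the dominant determinant
#' (the defining property of a gametophytic locus: every polyhaploid carries
#' it). `haploid_lethal` kills haploid (single-chromatid) gametes that carry
#' the dominant allele -- the transmission barrier seen when no haploid
#' carrier is ever recovered. `exclude_dominant` inverts the requirement and
#' models a negative-selectable transgene: survivors must lack the allele.
#' `viability_weights` multiplies a per-allele survival probability over the
#' alleles carried at `locus` (defaults to the selection locus), modelling
#' transmission bias that the cross itself cannot attribute to gametic versus
#' zygotic causes.
#'
#' @param require_dominant Logical.
#' @param haploid_lethal Logical.
#' @param exclude_dominant Logical.
#' @param viability_weights Named numeric vector in `[0, 1]`, names are allele
#'   labels; unlisted alleles weigh 1.
#' @param locus Marker name at which viability weights act; `NULL` means the
#'   gamete's selection locus.
#' @return A `selection_model`.
#' @export
selection_model <- function(require_dominant = TRUE, haploid_lethal = TRUE,
                            exclude_dominant = FALSE,
                            viability_weights = NULL, locus = NULL) {
  if (!is.null(viability_weights)) {
    if (is.null(names(viability_weights)) ||
        any(viability_weights < 0 | viability_weights > 1))
      .stop_ctx("viability_weights must be named and lie in [0, 1]")
  }
  if (require_dominant && exclude_dominant)
    .stop_ctx("require_dominant and exclude_dominant are mutually exclusive")
  structure(list(require_dominant = isTRUE(require_dominant),
                 haploid_lethal = isTRUE(haploid_lethal),
                 exclude_dominant = isTRUE(exclude_dominant),
                 viability_weights = viability_weights,
                 locus = locus),
            class = "selection_model")
}

# the three perfect pairings of four homologues into two bivalents
.pairings4 <- list(
  list(c(1L, 2L), c(3L, 4L)),
  list(c(1L, 3L), c(2L, 4L)),
  list(c(1L, 4L), c(2L, 3L))
)

# one transmitted chromatid from a bivalent of two homologues:
# crossover count ~ Poisson(map length in Morgans), positions uniform on the
# genetic scale, and the tracked chromatid switches homologue at every
# crossover; the starting homologue is fair. P(odd switches over d Morgans)
# = (1 - exp(-2d))/2, the Haldane mapping function.
.bivalent_chromatid <- function(homs, cM) {
  L <- (max(cM) - min(cM)) / 100  # Morgans
  start <- sample(2L, 1L)
  n_xo <- stats::rpois(1L, L)
  if (n_xo == 0L || L == 0) {
    origin <- rep(homs[start], length(cM))
    return(list(origin = origin, breakpoints = numeric(0)))
  }
  bp <- sort(stats::runif(n_xo, min(cM), max(cM)))
  below <- vapply(cM, function(p) sum(bp <= p), integer(1L))
  side <- (start - 1L + below) %% 2L + 1L
  list(origin = homs[side], breakpoints = bp)
}

#' Simulate one meiotic gamete from a tetraploid or diploid parent
#'
#' Meiosis is modelled at the level of bivalents. A tetraploid forms two
#' bivalents; under tetrasomic pairing the partition of the four homologues
#' is drawn uniformly from the three perfect pairings at every meiosis, while
#' disomic pairing uses one fixed partition. Crossover counts per bivalent
#' are Poisson in the bivalent's genetic length (no interference, no obligate
#' chiasma) and one chromatid per bivalent is transmitted, giving a diploid
#' gamete; a diploid parent forms one bivalent and a haploid gamete. With
#' probability `dr_rate` (double reduction, off by default) both transmitted
#' chromatids are drawn independently from the same bivalent.
#'
#' @param parent A `parent_genotype`.
#' @param mode `"tetrasomic"` or `"disomic"`.
#' @param partition For disomic mode, a list of two integer pairs exactly
#'   partitioning 1:4, e.g. `list(c(1, 2), c(3, 4))`.
#' @param dr_rate Double-reduction probability per meiosis (default 0).
#' @param seed Optional integer seed for this single gamete.
#' @return A `polyhaploid_record`: chromatid mosaics (homologue-of-origin per
#'   marker plus breakpoint positions in cM; true phase), the unphased
#'   observed genotype (allele pair per marker, sorted), the alleles at the
#'   selection locus, and bookkeeping fields.
#' @export
simulate_gamete <- function(parent, mode = c("tetrasomic", "disomic"),
                            partition = NULL, dr_rate = 0, seed = NULL) {
  stopifnot(inherits(parent, "parent_genotype"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  map <- parent$map
  cM <- map$gen_cM
  n_hom <- nrow(parent$homologues)

  if (n_hom == 2L) {
    chroms <- list(.bivalent_chromatid(c(1L, 2L), cM))
  } else {
    if (mode == "tetrasomic") {
      pairing <- .pairings4[[sample(3L, 1L)]]
    } else {
      if (is.null(partition)) partition <- list(c(1L, 2L), c(3L, 4L))
      flat <- as.integer(sort(unlist(partition)))
      if (length(partition) != 2L || !identical(flat, 1:4))
        .stop_ctx("partition must be two pairs exactly covering homologues 1:4")
      pairing <- lapply(partition, as.integer)
    }
    if (dr_rate > 0 && stats::runif(1L) < dr_rate) {
      b <- sample(2L, 1L)  # both chromatids from one bivalent
      chroms <- list(.bivalent_chromatid(pairing[[b]], cM),
                     .bivalent_chromatid(pairing[[b]], cM))
    } else {
      chroms <- lapply(pairing, .bivalent_chromatid, cM = cM)
    }
  }

  geno <- vapply(seq_along(chroms), function(i) {
    parent$homologues[cbind(chroms[[i]]$origin, seq_len(nrow(map)))]
  }, integer(nrow(map)))
  geno <- t(apply(matrix(geno, nrow = nrow(map)), 1L,
                  function(r) sort.int(r, na.last = TRUE)))
  if (length(chroms) == 1L) geno <- matrix(geno, ncol = 1L)
  rownames(geno) <- map$name

  sel <- match(parent$selection_locus, map$name)
  rec <- list(
    chromatids = chroms,
    genotype = geno,
    n_chromatids = length(chroms),
    selection_locus = parent$selection_locus,
    selection_alleles = geno[sel, ],
    dominant_allele = parent$dominant_allele,
    accepted = NA
  )
  class(rec) <- "polyhaploid_record"
  rec
}

#' Does a gamete survive gametophytic selection?
#'
#' Applies a [selection_model()] to a single gamete: rejected if the dominant
#' allele is required but absent; rejected if haploid-lethality applies and a
#' haploid gamete carries the dominant allele; rejected if a
#' negative-selection marker is carried; otherwise accepted with probability
#' equal to the product of the viability weights of the alleles carried at
#' the model's locus.
#'
#' @param gamete A `polyhaploid_record`.
#' @param model A `selection_model`.
#' @return Logical flag.
#' @export
passes_selection <- function(gamete, model) {
  stopifnot(inherits(gamete, "polyhaploid_record"),
            inherits(model, "selection_model"))
  carried <- gamete$selection_alleles
  has_dom <- !is.na(gamete$dominant_allele) &&
    any(!is.na(carried) & carried == gamete$dominant_allele)
  if (model$require_dominant && !has_dom) return(FALSE)
  if (model$exclude_dominant && has_dom) return(FALSE)
  if (model$haploid_lethal && gamete$n_chromatids == 1L && has_dom)
    return(FALSE)
  w <- model$viability_weights
  if (!is.null(w)) {
    locus <- model$locus %||% gamete$selection_locus
    alleles <- gamete$genotype[locus, ]
    prob <- prod(ifelse(is.na(alleles), 1,
                        ifelse(is.na(w[as.character(alleles)]), 1,
                               w[as.character(alleles)])))
    if (stats::runif(1L) > prob) return(FALSE)
  }
  TRUE
}

#' Simulate a selected polyhaploid population
#'
#' Rejection-samples gametes from `parent` until `N` pass the selection
#' model. Reproducible under `seed`; aborts with a diagnostic if the
#' generation cap is reached (acceptance impossible or vanishingly rare).
#'
#' @inheritParams simulate_gamete
#' @param model A [selection_model()].
#' @param N Number of accepted polyhaploids required.
#' @param seed Integer seed for the whole population.
#' @param max_generated Generation cap before aborting (default
#'   `max(10000, 1000 * N)`).
#' @return A `polyhaploid_population`: list with `records` (accepted
#'   `polyhaploid_record`s) and `meta` (`N_requested`, `N_accepted`,
#'   `N_generated`, `acceptance_rate`, `seed`, `mode`).
#' @export
simulate_population <- function(parent, model, N,
                                mode = c("tetrasomic", "disomic"),
                                partition = NULL, dr_rate = 0, seed = 1L,
                                max_generated = NULL) {
  mode <- match.arg(mode)
  if (N < 0) .stop_ctx("N must be non-negative")
  if (is.null(max_generated)) max_generated <- max(10000, 1000 * N)
  set.seed(seed)
  records <- vector("list", N)
  n_acc <- 0L
  n_gen <- 0L
  while (n_acc < N) {
    if (n_gen >= max_generated)
      .stop_ctx(sprintf(
        "generation cap reached: %d gametes generated, %d accepted; acceptance under this selection model appears impossible or vanishingly rare",
        n_gen, n_acc))
    g <- simulate_gamete(parent, mode, partition, dr_rate)
    n_gen <- n_gen + 1L
    if (passes_selection(g, model)) {
      g$accepted <- TRUE
      n_acc <- n_acc + 1L
      records[[n_acc]] <- g
    }
  }
  meta <- list(N_requested = as.integer(N), N_accepted = n_acc,
               N_generated = n_gen,
               acceptance_rate = if (n_gen) n_acc / n_gen else NA_real_,
               seed = seed, mode = mode)
  structure(list(records = records, meta = meta),
            class = "polyhaploid_population")
}

#' @export
print.polyhaploid_population <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "Polyhaploid population: %d accepted of %d generated (%.1f%%), mode %s, seed %s\n",
    m$N_accepted, m$N_generated, 100 * m$acceptance_rate, m$mode,
    format(m$seed)))
  invisible(x)
}

#' Estimate the gamete acceptance rate under a selection model
#'
#' Generates a fixed number of gametes (no rejection loop) and reports the
#' fraction passing selection, with the binomial standard error. With a
#' simplex dominant parent and `require_dominant`, the expectation is exactly
#' 1/2 under both pairing modes (no double reduction): the chromatid drawn
#' from the dominant homologue's bivalent carries it with probability 1/2.
#'
#' @inheritParams simulate_population
#' @param n_gametes Number of gametes to generate.
#' @return List with `rate`, `se`, `n`, `n_passed`.
#' @export
estimate_acceptance_rate <- function(parent, model, n_gametes,
                                     mode = c("tetrasomic", "disomic"),
                                     partition = NULL, dr_rate = 0,
                                     seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  passed <- 0L
  for (i in seq_len(n_gametes)) {
    g <- simulate_gamete(parent, mode, partition, dr_rate)
    if (passes_selection(g, model)) passed <- passed + 1L
  }
  rate <- passed / n_gametes
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_gametes),
       n = as.integer(n_gametes), n_passed = passed)
}

#' Expected seed recovery under spontaneous polyhaploidy plus selection
#'
#' Models the negative-selectable-marker route to a mapping population: each
#' sown seed is a spontaneous polyhaploid with probability
#' `polyhaploid_rate`; a polyhaploid survives if its (diploid) gamete
#' genotype passes `model`. With a simplex marker under tetrasomic
#' transmission and `exclude_dominant`, half the polyhaploids survive, so the
#' recovery rate is `polyhaploid_rate / 2` (0.5% at the canonical 1%).
#'
#' @inheritParams simulate_population
#' @param n_seeds Number of seeds sown.
#' @param polyhaploid_rate Spontaneous polyhaploid formation rate.
#' @return List with `rate` (surviving fraction of sown seed), `se`,
#'   `n_seeds`, `n_polyhaploid`, `n_surviving`.
#' @export
simulate_seed_recovery <- function(parent, model, n_seeds,
                                   polyhaploid_rate = 0.01,
                                   mode = c("tetrasomic", "disomic"),
                                   partition = NULL, dr_rate = 0, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  n_poly <- stats::rbinom(1L, n_seeds, polyhaploid_rate)
  surv <- 0L
  for (i in seq_len(n_poly)) {
    g <- simulate_gamete(parent, mode, partition, dr_rate)
    if (passes_selection(g, model)) surv <- surv + 1L
  }
  rate <- surv / n_seeds
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_seeds),
       n_seeds = as.integer(n_seeds), n_polyhaploid = n_poly,
       n_surviving = surv)
}

#' Long-format genotype table of a simulated population
#'
#' Converts a population to the package's genotype-table dialect: one row per
#' plant x locus with columns `plant_id`, `locus`, `allele_a`, `allele_b`
#' (sorted allele pair; `NA` for deleted/absent). With `phased = TRUE`, two
#' extra columns give the true chromatid-of-origin alleles.
#'
#' @param population A `polyhaploid_population`.
#' @param phased Include true-phase columns `chromatid_a`, `chromatid_b`.
#' @return A data frame.
#' @export
as_genotype_table <- function(population, phased = FALSE) {
  stopifnot(inherits(population, "polyhaploid_population"))
  recs <- population$records
  if (!length(recs)) {
    out <- data.frame(plant_id = character(0), locus = character(0),
                      allele_a = integer(0), allele_b = integer(0))
    return(out)
  }
  loci <- rownames(recs[[1L]]$genotype)
  n_loci <- length(loci)
  tabs <- lapply(seq_along(recs), function(i) {
    g <- recs[[i]]$genotype
    out <- data.frame(
      plant_id = sprintf("plant_%04d", i),
      locus = loci,
      allele_a = g[, 1L],
      allele_b = if (ncol(g) > 1L) g[, 2L] else NA_integer_,
      stringsAsFactors = FALSE
    )
    if (phased) {
      ch <- recs[[i]]$chromatids
      hom <- function(k) if (length(ch) >= k)
        vapply(seq_len(n_loci), function(j) ch[[k]]$origin[j], integer(1L))
      else rep(NA_integer_, n_loci)
      out$chromatid_a <- hom(1L)
      out$chromatid_b <- hom(2L)
    }
    out
  })
  do.call(rbind, tabs)
}
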