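#' Temporal profile archetypes
#'
#' The simulator draws genes from six archetypal mean trajectories over age,
#' mirroring the shapes seen in aging time courses: constant expression
#' (`flat`), gradual linear increase or decrease (`linear_up`,
#' `linear_down`), an exponential approach to a lowered asymptote
#' (`rapid_decay`, rapid early down-regulation that does not reach zero),
#' and Gaussian-bump trough or peak shapes (`u_shape`, `bell_shape`) with a
#' vertex age near median lifespan. `amplitude` is a relative effect size;
#' U/bell shapes require `vertexAge` and rapid decay requires `decayRate`
#' (per week).
#'
#' @param name one of `"flat"`, `"linear_up"`, `"linear_down"`,
#'   `"rapid_decay"`, `"u_shape"`, `"bell_shape"`.
#' @param baseline positive real, expected intensity on the RPKM scale.
#' @param amplitude relative effect size, `|amplitude| <= 5`.
#' @param vertexAge vertex (trough/peak) age in weeks, U/bell only.
#' @param decayRate decay rate per week, rapid decay only.
#' @return a validated list of class `"profileArchetype"`.
#' @export
profileArchetype <- function(name, baseline = 100, amplitude = 1,
                             vertexAge = NULL, decayRate = NULL) {
  name <- match.arg(name, c("flat", "linear_up", "linear_down",
                            "rapid_decay", "u_shape", "bell_shape"))
  if (!is.numeric(baseline) || baseline <= 0)
    stop("baseline must be positive")
  if (abs(amplitude) > 5) stop("|amplitude| must not exceed 5")
  if (name %in% c("u_shape", "bell_shape")) {
    if (is.null(vertexAge)) stop("vertexAge is required for ", name)
  } else if (!is.null(vertexAge)) {
    stop("vertexAge applies only to u_shape/bell_shape")
  }
  if (name == "rapid_decay") {
    if (is.null(decayRate) || decayRate <= 0)
      stop("a positive decayRate is required for rapid_decay")
  } else if (!is.null(decayRate)) {
    stop("decayRate applies only to rapid_decay")
  }
  structure(list(name = name, baseline = baseline, amplitude = amplitude,
                 vertexAge = vertexAge, decayRate = decayRate),
            class = "profileArchetype")
}

#' @rdname profileArchetype
#' @param baseline,vertexAge passed to each archetype.
#' @return `defaultArchetypes()`: a named list of the six archetypes with
#'   conventional effect sizes.
#' @export
defaultArchetypes <- function(baseline = 100, vertexAge = 25) {
  list(
    flat        = profileArchetype("flat", baseline, amplitude = 0),
    linear_up   = profileArchetype("linear_up", baseline, amplitude = 1),
    linear_down = profileArchetype("linear_down", baseline, amplitude = 0.8),
    rapid_decay = profileArchetype("rapid_decay", baseline, amplitude = 0.8,
                                   decayRate = 0.3),
    u_shape     = profileArchetype("u_shape", baseline, amplitude = 1,
                                   vertexAge = vertexAge),
    bell_shape  = profileArchetype("bell_shape", baseline, amplitude = 1,
                                   vertexAge = vertexAge))
}

#' Expected expression of an archetype at a given age
#'
#' Evaluates the archetype's mean trajectory (RPKM scale) at `age`, given
#' the ordered design ages (which set the normalization span). With
#' `a0 = min(ages)`, `aMax = max(ages)` and `tau = (age - vertex)/(aMax - a0)`:
#' flat is `baseline`; linear up/down are
#' `baseline * (1 +/- amplitude * (age - a0)/(aMax - a0))`; rapid decay is
#' `baseline * ((1 - amplitude) + amplitude * exp(-decayRate * (age - a0)))`;
#' U and bell are `baseline * exp(+amplitude * tau^2)` and
#' `baseline * exp(-amplitude * tau^2)`. The result is clamped below at
#' `baseline * 1e-3` so simulated intensities stay positive.
#'
#' @param archetype a [profileArchetype()].
#' @param age age in weeks (vectorized), within `range(ages)`.
#' @param ages the ordered design ages.
#' @return positive numeric vector of expected RPKM.
#' @export
archetypeMean <- function(archetype, age, ages) {
  stopifnot(inherits(archetype, "profileArchetype"))
  a0 <- min(ages); aMax <- max(ages)
  if (any(age < a0 - 1e-9) || any(age > aMax + 1e-9))
    stop("age outside the design range [", a0, ", ", aMax, "]")
  b <- archetype$baseline; A <- archetype$amplitude
  frac <- (age - a0) / (aMax - a0)
  mu <- switch(archetype$name,
    flat        = rep(b, length(age)),
    linear_up   = b * (1 + A * frac),
    linear_down = b * (1 - A * frac),
    rapid_decay = b * ((1 - A) + A * exp(-archetype$decayRate * (age - a0))),
    u_shape     = b * exp(+A * ((age - archetype$vertexAge) / (aMax - a0))^2),
    bell_shape  = b * exp(-A * ((age - archetype$vertexAge) / (aMax - a0))^2))
  pmax(mu, b * 1e-3)
}

#' Simulation configuration
#'
#' Defaults reproduce the study design emulated throughout the package:
#' five age groups at 5, 12, 20, 27 and 39 weeks with five biological
#' replicates each, moderate bulk-RNA-seq overdispersion
#' (negative-binomial size 10), desk-scale library sizes and transcript
#' lengths.
#'
#' @param ages strictly increasing ages in weeks.
#' @param replicatesPerAge replicates per age group.
#' @param genesPerArchetype named integer vector, genes per archetype; names
#'   must be a subset of the archetype names.
#' @param nbDispersion negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param librarySizeRange,geneLengthRange uniform sampling ranges for
#'   per-sample library sizes (reads) and per-gene lengths (bases).
#' @param archetypes named list of [profileArchetype()] objects.
#' @return list of class `"simConfig"`.
#' @export
simConfig <- function(ages = c(5, 12, 20, 27, 39), replicatesPerAge = 5,
                      genesPerArchetype = c(flat = 200, linear_up = 200,
                                            linear_down = 200,
                                            rapid_decay = 200,
                                            u_shape = 200, bell_shape = 200),
                      nbDispersion = 10,
                      librarySizeRange = c(8e5, 1.2e6),
                      geneLengthRange = c(500, 5000),
                      archetypes = defaultArchetypes()) {
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly increasing")
  if (replicatesPerAge < 1) stop("replicatesPerAge must be positive")
  if (is.null(names(genesPerArchetype)) ||
      !all(names(genesPerArchetype) %in% names(archetypes)))
    stop("genesPerArchetype names must match archetype names")
  if (any(genesPerArchetype < 0) || sum(genesPerArchetype) < 1)
    stop("at least one gene must be simulated")
  if (nbDispersion <= 0) stop("nbDispersion must be positive")
  for (rg in list(librarySizeRange, geneLengthRange))
    if (length(rg) != 2L || any(rg <= 0) || rg[1L] > rg[2L])
      stop("ranges must be positive with low <= high")
  structure(list(ages = ages, replicatesPerAge = as.integer(replicatesPerAge),
                 genesPerArchetype = genesPerArchetype,
                 nbDispersion = nbDispersion,
                 librarySizeRange = librarySizeRange,
                 geneLengthRange = geneLengthRange,
                 archetypes = archetypes),
            class = "simConfig")
}

#' Simulate an age-structured RNA-seq count matrix with known truth
#'
#' Draws `counts(g, s) ~ NB(mean = L_s * (length_g / 1e3) *
#' archetypeMean(g, age_s) / 1e6, size = nbDispersion)`, so that the
#' expected RPKM of gene `g` at age `a` is exactly its archetype mean.
#' Library sizes and gene lengths are drawn uniformly from the configured
#' ranges. All randomness flows through one generator stream seeded with
#' `seed`, so identical `(config, seed)` pairs give bitwise-identical
#' output. Flat genes are the null: their truth-table `is_deg` is `FALSE`.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return list with elements `experiment` (an [AgingExperiment-class]),
#'   `truth` (data.frame: `gene_id`, `archetype`, `vertex_age`, `is_deg`)
#'   and `seed`.
#' @export
simulateAgingCounts <- function(config = simConfig(), seed = 1) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(as.integer(seed))
  nPer <- config$genesPerArchetype[config$genesPerArchetype > 0]
  arch <- rep(names(nPer), nPer)
  nG <- length(arch)
  geneIds <- sprintf("g%0*d", nchar(nG) + 1L, seq_len(nG))
  sampleAge <- rep(config$ages, each = config$replicatesPerAge)
  sampleRep <- rep(seq_len(config$replicatesPerAge), length(config$ages))
  sampleIds <- sprintf("s%02dw_r%d", sampleAge, sampleRep)
  nS <- length(sampleIds)

  lens <- round(stats::runif(nG, config$geneLengthRange[1L],
                             config$geneLengthRange[2L]))
  libs <- round(stats::runif(nS, config$librarySizeRange[1L],
                             config$librarySizeRange[2L]))
  meanByAge <- vapply(config$ages, function(a) {
    vapply(arch, function(nm)
      archetypeMean(config$archetypes[[nm]], a, config$ages), numeric(1))
  }, numeric(nG))                                    # genes x ages
  amean <- meanByAge[, match(sampleAge, config$ages), drop = FALSE]
  mu <- amean * outer(lens / 1e3, libs / 1e6)  # E[rpkm] = archetype mean
  counts <- matrix(stats::rnbinom(nG * nS, mu = as.vector(mu),
                                  size = config$nbDispersion),
                   nrow = nG, dimnames = list(geneIds, sampleIds))
  truth <- data.frame(
    gene_id = geneIds, archetype = arch,
    vertex_age = vapply(arch, function(nm) {
      v <- config$archetypes[[nm]]$vertexAge
      if (is.null(v)) NA_real_ else v
    }, numeric(1)),
    is_deg = arch != "flat", row.names = NULL, stringsAsFactors = FALSE)
  ae <- AgingExperiment(counts, geneLengths = lens,
                        ageWeeks = sampleAge, replicate = sampleRep)
  # keep the generating library sizes: column totals of a small simulated
  # matrix are not an estimate of them
  SummarizedExperiment::colData(ae)$library_size <- libs
  list(experiment = ae, truth = truth, seed = as.integer(seed))
}

#' Simulate gene-set collections aligned with the archetype truth
#'
#' Builds one set per archetype containing a fixed fraction (default 80%)
#' of that archetype's genes plus a small random contamination (default 5%
#' of the set size, drawn from all simulated genes), and optionally
#' `nRandomSets` sets of uniformly drawn genes that carry no signal —
#' suitable as a null for false-positive accounting.
#'
#' @param truth the truth table from [simulateAgingCounts()].
#' @param nRandomSets number of pure-noise sets.
#' @param seed integer seed.
#' @param coverage fraction of an archetype's genes included in its set.
#' @param contamination fraction of the set size added as random genes.
#' @param randomSetSize size of each random set.
#' @return a GMT-style named list of member vectors (see [readGmt()]).
#' @export
simulateGeneSets <- function(truth, nRandomSets = 0, seed = 1,
                             coverage = 0.8, contamination = 0.05,
                             randomSetSize = 100) {
  if (!nrow(truth)) stop("truth table is empty")
  set.seed(as.integer(seed))
  allGenes <- truth$gene_id
  sets <- list()
  for (nm in unique(truth$archetype)) {
    members <- truth$gene_id[truth$archetype == nm]
    core <- sort(sample(members, max(1L, round(coverage * length(members)))))
    nCont <- round(contamination * length(core))
    cont <- if (nCont > 0) sample(setdiff(allGenes, core), nCont)
            else character()
    sets[[paste0("SET_", nm)]] <- c(core, cont)
  }
  if (nRandomSets > 0) {
    for (i in seq_len(nRandomSets)) {
      sets[[sprintf("RANDOM_%03d", i)]] <-
        sort(sample(allGenes, min(randomSetSize, length(allGenes))))
    }
  }
  attr(sets, "descriptions") <- stats::setNames(
    ifelse(startsWith(names(sets), "SET_"),
           "archetype-derived set", "uniform random set"),
    names(sets))
  sets
}
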