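#' StatePattern: one latent connectivity state
#'
#' A dynamic functional state of the generator: a region x region correlation
#' matrix (positive semi-definite, unit diagonal) plus a structure tag. The
#' `homotopicExcess` slot stores how much each homotopic edge exceeds the
#' state's structural background; the dose effect scales exactly this excess,
#' so states without privileged homotopic coupling are untouched by dose.
#'
#' @slot patternId integer id.
#' @slot covariance correlation matrix (R x R).
#' @slot structureTag one of `"modular"`, `"homotopic"`, `"cortico-thalamic"`,
#'   `"unstructured"`.
#' @slot homotopicExcess R x R matrix, zero off the homotopic edges.
#' @export
setClass("StatePattern",
  representation(patternId = "integer", covariance = "matrix",
                 structureTag = "character", homotopicExcess = "matrix"))

setValidity("StatePattern", function(object) {
  msg <- NULL
  m <- object@covariance
  if (max(abs(m - t(m))) > 1e-10) msg <- c(msg, "covariance must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) msg <- c(msg, "unit diagonal required (correlation scale)")
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, "covariance must be PSD within 1e-8")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "StatePattern", function(object) {
  cat(sprintf("StatePattern #%d (%s), %d regions\n", object@patternId,
              object@structureTag, nrow(object@covariance)))
})

#' Default latent-state specifications
#'
#' Six states emulating what dictionary learning recovers from dose-graded
#' mouse rs-fMRI: four modular states engaging cortical, cortico-subcortical,
#' prefrontal and cortico-thalamic module combinations, one globally
#' homotopic state, and one spatially unstructured state with uniform
#' off-diagonal correlation. Each spec lists the engaged modules, the
#' within/between-module and homotopic correlations, and a background level.
#'
#' @param atlas a [ModuleAtlas-class] (module names must match the specs;
#'   defaults assume [buildAtlas()] defaults).
#' @return list of specs consumable by [makeStateCovariances()].
#' @export
defaultStateSpecs <- function(atlas = buildAtlas()) {
  mods <- unique(moduleOf(atlas))
  stopifnot(all(c("LCN", "ACN", "PFN", "SuCN", "ThN") %in% mods))
  list(
    list(name = "cortical",        tag = "modular",
         modules = c("LCN", "ACN"), within = 0.50, between = 0.40,
         homotopic = 0.70, base = 0.05),
    list(name = "cortico-subcortical", tag = "modular",
         modules = c("SuCN", "LCN"), within = 0.45, between = 0.35,
         homotopic = 0.60, base = 0.05),
    list(name = "prefrontal",      tag = "modular",
         modules = c("PFN", "ACN"), within = 0.45, between = 0.35,
         homotopic = 0.60, base = 0.05),
    list(name = "cortico-thalamic", tag = "cortico-thalamic",
         modules = c("ThN", "PFN"), within = 0.40, between = 0.35,
         homotopic = 0.50, base = 0.05),
    list(name = "homotopic",       tag = "homotopic",
         modules = mods, within = 0.15, between = 0.05,
         homotopic = 0.75, base = 0.05),
    list(name = "unstructured",    tag = "unstructured",
         modules = character(0), within = 0, between = 0,
         homotopic = NA_real_, base = 0.30)
  )
}

# Build the block correlation matrix for one spec; homotopic = NA means "no
# privileged homotopic coupling" (pairs keep their block value).
buildBlockCorrelation <- function(atlas, spec, withHomotopic = TRUE) {
  regions <- regionLabels(atlas)
  R <- length(regions)
  mod <- moduleOf(atlas)
  m <- matrix(spec$base, R, R, dimnames = list(regions, regions))
  eng <- spec$modules
  if (length(eng) > 0) {
    for (a in eng) for (b in eng) {
      rho <- if (a == b) spec$within else spec$between
      m[mod == a, mod == b] <- rho
    }
  }
  if (withHomotopic && !is.na(spec$homotopic)) {
    p <- homotopicPairs(atlas)
    inEng <- mod[p[, 1L]] %in% eng
    for (k in which(inEng | length(eng) == 0)) {
      m[p[k, 1L], p[k, 2L]] <- m[p[k, 2L], p[k, 1L]] <- spec$homotopic
    }
  }
  diag(m) <- 1
  m
}

#' Build latent-state correlation matrices
#'
#' Turns per-state block specifications (within-module, between-module,
#' homotopic and background correlations) into valid [StatePattern-class]
#' objects. Constructions that are not positive semi-definite are projected
#' to the nearest PSD matrix by eigenvalue clipping and renormalised to unit
#' diagonal; the Frobenius projection distance is kept as the
#' `"psd_distance"` attribute of each covariance.
#'
#' @param atlas a [ModuleAtlas-class].
#' @param specs list of specs as in [defaultStateSpecs()].
#' @param tol PSD tolerance on the minimum eigenvalue after projection.
#' @return list of [StatePattern-class], one per spec.
#' @export
makeStateCovariances <- function(atlas, specs = defaultStateSpecs(atlas),
                                 tol = 1e-8) {
  lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    full <- buildBlockCorrelation(atlas, spec, withHomotopic = TRUE)
    noHom <- buildBlockCorrelation(atlas, spec, withHomotopic = FALSE)
    excess <- full - noHom
    proj <- nearestPSD(full, tol = tol)
    dist <- attr(proj, "psd_distance")
    if (dist > 0) proj <- cov2cor(proj)
    if (min(eigen(proj, symmetric = TRUE, only.values = TRUE)$values) < -tol)
      stop("state '", spec$name, "' is not PSD even after projection")
    attr(proj, "psd_distance") <- dist
    new("StatePattern", patternId = as.integer(i), covariance = proj,
        structureTag = spec$tag, homotopicExcess = excess)
  })
}

#' CohortConfig: parameters of the synthetic dose cohort
#'
#' Encodes the study conditions the generator emulates: scan length and TR,
#' group sizes, the dose levels, the dose-to-homotopic-correlation map
#' (stationary effect) and the dose-to-state-occupancy map (dynamic effect),
#' latent dwell time, smoothing and noise levels, design mode and the master
#' seed.
#'
#' @slot nSubjects subjects per dose.
#' @slot doses dose levels (% isoflurane).
#' @slot nTimepoints timepoints per scan.
#' @slot tr repetition time, seconds.
#' @slot dwellMean mean latent-state dwell time, timepoints.
#' @slot homotopicRho named numeric, target homotopic correlation per dose.
#' @slot occupancy doses x states matrix of state occupancies (rows sum to 1).
#' @slot noiseSd additive white-noise SD (signal is unit variance).
#' @slot hrfFwhm FWHM (seconds) of the Gaussian temporal kernel standing in
#'   for the hemodynamic response; 0 disables smoothing.
#' @slot subjectEffectSd SD of the per-subject modulation of homotopic
#'   coupling (shared across doses in the longitudinal design).
#' @slot design `"longitudinal"` or `"cross_sectional"`.
#' @slot seed master seed.
#' @export
setClass("CohortConfig",
  representation(nSubjects = "integer", doses = "numeric",
                 nTimepoints = "integer", tr = "numeric", dwellMean = "numeric",
                 homotopicRho = "numeric", occupancy = "matrix",
                 noiseSd = "numeric", hrfFwhm = "numeric",
                 subjectEffectSd = "numeric", design = "character",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- NULL
  if (object$nTimepoints < 2) msg <- c(msg, "need at least 2 timepoints")
  if (object@dwellMean < 1) msg <- c(msg, "dwellMean must be >= 1 timepoint")
  if (!all(abs(rowSums(object@occupancy) - 1) < 1e-8))
    msg <- c(msg, "occupancy rows must sum to 1")
  if (any(object@occupancy < 0)) msg <- c(msg, "occupancy must be nonnegative")
  if (nrow(object@occupancy) != length(object@doses))
    msg <- c(msg, "one occupancy row per dose required")
  if (!all(abs(object@homotopicRho) < 1)) msg <- c(msg, "homotopicRho must lie in (-1, 1)")
  if (!setequal(names(object@homotopicRho), as.character(object@doses)))
    msg <- c(msg, "homotopicRho must be named by the dose levels")
  if (!object@design %in% c("longitudinal", "cross_sectional"))
    msg <- c(msg, "design must be 'longitudinal' or 'cross_sectional'")
  if (is.null(msg)) TRUE else msg
})

setMethod("$", "CohortConfig", function(x, name) slot(x, name))

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d subjects x %d doses (%s%%), T = %d, TR = %g s, %s design\n",
              object@nSubjects, length(object@doses),
              paste(object@doses, collapse = ", "),
              object@nTimepoints, object@tr, object@design))
  cat("homotopic rho by dose:",
      paste(sprintf("%s -> %.2f", names(object@homotopicRho), object@homotopicRho),
            collapse = ", "), "\n")
})

#' Construct a cohort configuration
#'
#' Defaults reproduce the study conditions the generator targets: 12 subjects
#' per dose at 1.1/1.3/1.5/2.0% isoflurane, 360 timepoints at TR = 1 s, six
#' latent states with mean dwell 40 timepoints, homotopic correlation falling
#' from 0.70 at the lowest dose to 0.15 at the highest, and state occupancy
#' shifting from the modular states toward the unstructured state with dose.
#'
#' @param nSubjects subjects per dose (default 12).
#' @param doses dose levels in percent (default `c(1.1, 1.3, 1.5, 2.0)`).
#' @param nTimepoints timepoints (default 360).
#' @param tr repetition time in seconds (default 1).
#' @param dwellMean mean state dwell in timepoints (default 40).
#' @param homotopicRho named numeric map dose -> homotopic correlation;
#'   default decreasing `c("1.1"=0.70, "1.3"=0.55, "1.5"=0.40, "2"=0.15)`
#'   (renamed to match `doses`).
#' @param occupancy doses x states occupancy matrix; default 6-state simplex
#'   shifting weight to the final (unstructured) state with dose.
#' @param noiseSd additive noise SD (default 0.1).
#' @param hrfFwhm temporal-kernel FWHM in seconds (default 1, the scale of
#'   the fast rodent hemodynamic response at high field).
#' @param subjectEffectSd per-subject homotopic modulation SD (default 0.1).
#' @param design `"longitudinal"` (default) or `"cross_sectional"`.
#' @param seed master seed (default 1).
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nSubjects = 12L, doses = c(1.1, 1.3, 1.5, 2.0),
                         nTimepoints = 360L, tr = 1, dwellMean = 40,
                         homotopicRho = NULL, occupancy = NULL,
                         noiseSd = 0.1, hrfFwhm = 1.0, subjectEffectSd = 0.1,
                         design = "longitudinal", seed = 1L) {
  nd <- length(doses)
  if (is.null(homotopicRho)) {
    if (nd == 4L) homotopicRho <- c(0.70, 0.55, 0.40, 0.15)
    else homotopicRho <- seq(0.70, 0.15, length.out = nd)
  }
  if (is.null(names(homotopicRho))) names(homotopicRho) <- as.character(doses)
  if (is.null(occupancy)) {
    base <- rbind(c(0.25, 0.23, 0.16, 0.12, 0.14, 0.10),
                  c(0.20, 0.19, 0.15, 0.12, 0.13, 0.21),
                  c(0.14, 0.14, 0.12, 0.10, 0.10, 0.40),
                  c(0.05, 0.05, 0.07, 0.06, 0.06, 0.71))
    occupancy <- if (nd == 4L) base else {
      # interpolate rows along dose rank for non-default dose grids
      idx <- seq(1, 4, length.out = nd)
      out <- t(vapply(idx, function(i) {
        lo <- floor(i); hi <- ceiling(i); w <- i - lo
        (1 - w) * base[lo, ] + w * base[hi, ]
      }, numeric(6)))
      out / rowSums(out)
    }
  }
  rownames(occupancy) <- as.character(doses)
  new("CohortConfig", nSubjects = as.integer(nSubjects), doses = doses,
      nTimepoints = as.integer(nTimepoints), tr = tr, dwellMean = dwellMean,
      homotopicRho = homotopicRho, occupancy = occupancy, noiseSd = noiseSd,
      hrfFwhm = hrfFwhm, subjectEffectSd = subjectEffectSd,
      design = design, seed = as.integer(seed))
}

#' Sample a semi-Markov latent state sequence
#'
#' Builds a sequence of state segments with geometric dwell times (mean
#' `dwellMean`). By default (`quota = TRUE`) each state's total time budget
#' is fixed at `occupancy * T` (largest-remainder rounding) and filled with
#' geometric segments before all segments are interleaved in random order,
#' so every scan realises the target occupancy exactly -- the per-scan state
#' exposure is a design quantity, not an extra noise source. With
#' `quota = FALSE` segment states are drawn independently from `occupancy`
#' (free-running; label frequencies then only converge to the occupancy in
#' the long run).
#'
#' @param nTimepoints sequence length T.
#' @param occupancy probability simplex over states.
#' @param dwellMean mean dwell time in timepoints (>= 1).
#' @param seed RNG seed.
#' @param quota match each scan's realised occupancy to the target exactly
#'   (default TRUE).
#' @return integer vector of length T with labels in `1..K`; attribute
#'   `"segments"` holds the (state, length) run-length encoding.
#' @export
sampleStateSequence <- function(nTimepoints, occupancy, dwellMean = 40,
                                seed = 1L, quota = TRUE) {
  stopifnot(dwellMean >= 1, all(occupancy >= 0),
            abs(sum(occupancy) - 1) < 1e-8, nTimepoints >= 1)
  K <- length(occupancy)
  withSeed(seed, {
    if (quota) {
      # largest-remainder apportionment of timepoints to states
      raw <- occupancy * nTimepoints
      budget <- floor(raw)
      short <- nTimepoints - sum(budget)
      if (short > 0) {
        extra <- order(raw - budget, decreasing = TRUE)[seq_len(short)]
        budget[extra] <- budget[extra] + 1L
      }
      states <- integer(0); lens <- integer(0)
      for (k in seq_len(K)) {
        left <- budget[k]
        while (left > 0L) {
          len <- min(1L + rgeom(1L, prob = 1 / dwellMean), left)
          states <- c(states, k); lens <- c(lens, len)
          left <- left - len
        }
      }
      ord <- sample.int(length(states))
      states <- states[ord]; lens <- lens[ord]
      labels <- rep.int(states, lens)
    } else {
      labels <- integer(0)
      states <- integer(0); lens <- integer(0)
      while (length(labels) < nTimepoints) {
        s <- sample.int(K, 1L, prob = occupancy)
        len <- min(1L + rgeom(1L, prob = 1 / dwellMean),
                   nTimepoints - length(labels))
        labels <- c(labels, rep.int(s, len))
        states <- c(states, s); lens <- c(lens, len)
      }
    }
    structure(labels, segments = cbind(state = states, length = lens),
              dwellMean = dwellMean)
  })
}

# Gaussian temporal smoothing of each column; kernel sd in samples, truncated
# at 4 sd, edge-renormalised; output rescaled to preserve unit variance of
# white input (interior points).
gaussSmoothColumns <- function(Y, sdSamples) {
  if (sdSamples <= 0) return(Y)
  h <- max(1L, ceiling(4 * sdSamples))
  w <- exp(-0.5 * ((-h:h) / sdSamples)^2)
  w <- w / sum(w)
  T <- nrow(Y)
  out <- matrix(0, T, ncol(Y))
  norm <- numeric(T)
  for (k in -h:h) {
    src <- (1 + max(0, -k)):(T - max(0, k))
    dst <- src + k
    wk <- w[k + h + 1L]
    out[dst, ] <- out[dst, ] + wk * Y[src, ]
    norm[dst] <- norm[dst] + wk
  }
  out <- out / norm
  out / sqrt(sum(w^2))
}

# Dose-adjusted covariance of one state: homotopic excess scaled by `factor`,
# PSD-projected and renormalised to unit diagonal.
doseAdjustedCovariance <- function(state, factor) {
  m <- state@covariance + (factor - 1) * state@homotopicExcess
  m <- nearestPSD(m)
  d <- attr(m, "psd_distance")
  if (d > 0) m <- cov2cor(m)
  attr(m, "psd_distance") <- NULL
  m
}

#' Simulate one subject's time series
#'
#' At each timepoint the signal is drawn from the active latent state's
#' correlation matrix, with the homotopic excess of every state scaled by the
#' dose-dependent factor `homotopicRho(dose) / homotopicRho(lowest dose)`
#' (times the subject's own modulation). A truncated Gaussian temporal kernel
#' (`hrfFwhm`) then stands in for hemodynamic smoothing, and white noise of
#' SD `noiseSd` is added.
#'
#' @param atlas a [ModuleAtlas-class].
#' @param states list of [StatePattern-class].
#' @param sequence integer state labels of length `config$nTimepoints`
#'   (see [sampleStateSequence()]).
#' @param doseLevel dose (%); must be a key of `config@homotopicRho`.
#' @param config a [CohortConfig-class].
#' @param seed RNG seed for this subject.
#' @param subjectEffect per-subject multiplier applied to the dose factor
#'   (default 1).
#' @param subject,group labels stored on the result.
#' @return a [SubjectTimeSeries-class].
#' @export
simulateSubject <- function(atlas, states, sequence, doseLevel, config,
                            seed = 1L, subjectEffect = 1,
                            subject = "subj", group = "") {
  key <- as.character(doseLevel)
  if (!key %in% names(config@homotopicRho))
    stop("dose ", doseLevel, " is not in the configured homotopicRho map")
  T <- config$nTimepoints
  if (length(sequence) != T) stop("sequence length must equal config nTimepoints")
  refRho <- config@homotopicRho[[as.character(min(config@doses))]]
  factor <- config@homotopicRho[[key]] / refRho * subjectEffect
  factor <- min(max(factor, 0), 1.5)
  R <- length(regionLabels(atlas))
  used <- sort(unique(sequence))
  chols <- lapply(used, function(k)
    chol(doseAdjustedCovariance(states[[k]], factor) + diag(1e-10, R)))
  names(chols) <- as.character(used)
  withSeed(seed, {
    Z <- matrix(rnorm(T * R), T, R)
    Y <- matrix(0, T, R)
    for (k in used) {
      idx <- which(sequence == k)
      Y[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[as.character(k)]]
    }
    if (config$hrfFwhm > 0)
      Y <- gaussSmoothColumns(Y, config$hrfFwhm / (2.3548 * config$tr))
    if (config$noiseSd > 0)
      Y <- Y + config$noiseSd * matrix(rnorm(T * R), T, R)
    colnames(Y) <- regionLabels(atlas)
    subjectTimeSeries(Y, tr = config$tr, subject = subject,
                      dose = doseLevel, group = group)
  })
}

#' Simulate a full dose cohort with exported ground truth
#'
#' Generates `nSubjects` scans per dose level under the configured latent
#' states. In the longitudinal design the same subject ids recur across doses
#' and each subject's homotopic modulation is shared across its scans; in the
#' cross-sectional design subjects are distinct per dose. All randomness
#' derives deterministically from `config@seed`, so any subset of subjects
#' reproduces independently of the rest.
#'
#' @param config a [CohortConfig-class].
#' @param atlas a [ModuleAtlas-class] (default [buildAtlas()]).
#' @param states list of [StatePattern-class]
#'   (default `makeStateCovariances(atlas)`).
#' @return an object of class `"SyntheticCohort"`: list with elements
#'   `subjects` (list of [SubjectTimeSeries-class]), `atlas`, `config`,
#'   `states`, and `truth` (state patterns, per-subject state sequences,
#'   occupancy and homotopic-rho maps).
#' @export
simulateCohort <- function(config = cohortConfig(), atlas = buildAtlas(),
                           states = makeStateCovariances(atlas)) {
  validObject(config)
  K <- length(states)
  if (ncol(config@occupancy) != K)
    stop("occupancy has ", ncol(config@occupancy), " columns but ", K, " states supplied")
  doses <- config@doses
  subjects <- list()
  sequences <- list()
  effects <- vapply(seq_len(config$nSubjects), function(s)
    withSeed(subSeed(config$seed, 0L, s), 1 + config$subjectEffectSd * rnorm(1L)),
    numeric(1))
  for (d in seq_along(doses)) {
    occ <- config@occupancy[d, ]
    for (s in seq_len(config$nSubjects)) {
      id <- if (config$design == "longitudinal") sprintf("s%02d", s)
            else sprintf("d%d_s%02d", d, s)
      eff <- if (config$design == "longitudinal") effects[s]
             else withSeed(subSeed(config$seed, d, s) + 7L,
                           1 + config$subjectEffectSd * rnorm(1L))
      seqSeed <- subSeed(config$seed, d, s) + 1L
      subjSeed <- subSeed(config$seed, d, s) + 2L
      sq <- sampleStateSequence(config$nTimepoints, occ, config$dwellMean, seqSeed)
      ts <- simulateSubject(atlas, states, sq, doses[d], config,
                            seed = subjSeed, subjectEffect = eff,
                            subject = id, group = config$design)
      tag <- sprintf("dose%s_%s", doses[d], id)
      subjects[[tag]] <- ts
      sequences[[tag]] <- as.integer(sq)
    }
  }
  truth <- list(
    statePatterns = lapply(states, function(s) s@covariance),
    stateTags = vapply(states, function(s) s@structureTag, character(1)),
    sequences = sequences,
    occupancy = config@occupancy,
    homotopicRho = config@homotopicRho,
    subjectEffects = effects,
    seed = config$seed)
  structure(list(subjects = subjects, atlas = atlas, config = config,
                 states = states, truth = truth),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d scans, %d regions\n",
              length(x$subjects), length(regionLabels(x$atlas))))
  if (!is.null(x$config))
    cat(sprintf("  %d doses x %d subjects, %s design\n", length(x$config@doses),
                x$config$nSubjects, x$config$design))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Lays out one TSV per scan plus `atlas.json`, `config.json` and
#' `truth.json` (ground-truth state patterns and sequences), all plain text.
#'
#' @param cohort a `"SyntheticCohort"` from [simulateCohort()].
#' @param dir output directory (created).
#' @return `writeCohort` returns `dir` invisibly; `readCohort` the cohort
#'   list (without the generator state objects).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tag in names(cohort$subjects))
    writeTimeSeriesTSV(cohort$subjects[[tag]], file.path(dir, paste0(tag, ".tsv")))
  writeAtlasJSON(cohort$atlas, file.path(dir, "atlas.json"))
  cfg <- cohort$config
  jsonlite::write_json(list(
    nSubjects = cfg$nSubjects, doses = cfg@doses, nTimepoints = cfg$nTimepoints,
    tr = cfg$tr, dwellMean = cfg$dwellMean,
    homotopicRho = as.list(cfg@homotopicRho),
    occupancy = unname(apply(cfg@occupancy, 1, as.list)),
    noiseSd = cfg$noiseSd, hrfFwhm = cfg$hrfFwhm,
    subjectEffectSd = cfg$subjectEffectSd, design = cfg$design,
    seed = cfg$seed), file.path(dir, "config.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, matrix = "rowmajor",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  subjects <- lapply(files, readTimeSeriesTSV)
  names(subjects) <- sub("\\.tsv$", "", basename(files))
  atlas <- readAtlasJSON(file.path(dir, "atlas.json"))
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else NULL
  structure(list(subjects = subjects, atlas = atlas, truth = truth),
            class = "SyntheticCohort")
}
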