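#' Configuration of the synthetic titration ground truth
#'
#' Defines the planted model from which every observable is emitted: a
#' numbered sequence, a nucleation segment, a per-residue incorporation
#' stage (the condition index at which the residue's peaks vanish;
#' `Inf` = stays flexible; `0` = never observable, used for the first
#' residue whose free alpha-amine carries no amide proton), a helix
#' propensity profile, and the emission/noise parameters.
#'
#' The default configuration reproduces the geometry of a 137-residue
#' coiled-coil construct: prolines at 12, 38 and 67, nucleation segment
#' 109-116, a flexible N-terminal tail 2-32 that never joins the assembly,
#' and a six-step DMSO ladder (100/90/85/80/70/50 percent). The fixture
#' sequence itself is synthetic (generated here), carrying those landmarks.
#'
#' @param n_res Number of residues (default 137).
#' @param sequence Optional residue string; default: a generated sequence
#'   with the landmark prolines.
#' @param prolines Proline positions (default 12, 38, 67).
#' @param nucleation Closed interval `c(start, end)` of the nucleation
#'   segment (default `c(109, 116)`); must not touch the chain termini.
#' @param flexible Closed interval that never joins the assembly (default
#'   `c(2, 32)`); `NULL` for none.
#' @param stage_plan Named list mapping stage index (as character) to a
#'   list of closed intervals; `NULL` uses the default staged plan for the
#'   default geometry, or a radiating plan (elongation in both directions
#'   from the nucleation segment at `elongation_rate` residues per
#'   condition) for custom geometries.
#' @param elongation_rate Residues per condition step for radiating plans.
#' @param dmso_fractions Condition ladder (strictly decreasing).
#' @param temperature_c,field_mhz Condition metadata.
#' @param helix_propensity Per-residue propensity in `[0, 1]`; scalar,
#'   full-length vector, or `NULL` for the default profile (0 in the
#'   N-terminal 40 residues, 1 in 41-121, 0.7 beyond).
#' @param helix_offset_ppm Calpha secondary shift at full folding
#'   (default 2.8 ppm, a typical fully-helical magnitude).
#' @param shift_sigma_ppm Gaussian noise on emitted shifts (default 0.2).
#' @param intensity_sigma_frac Fractional Gaussian noise on CPMG
#'   intensities (default 0.02).
#' @param j_sigma_hz Gaussian noise on couplings (default 0.3).
#' @param j_coil_hz,j_helix_hz Coupling endpoints of the coil-to-helix
#'   transition (defaults 7 and 4 Hz).
#' @param j_floor_hz Resolution floor below which a splitting is emitted as
#'   unresolved (default 3 Hz).
#' @param r2_base_s,r2_exchange_boost_s Baseline R2 and the exchange boost
#'   added to residues about to be incorporated (defaults 3 and 12 1/s).
#' @param boost_window A residue is boosted at condition `k` when its stage
#'   lies in `(k, k + boost_window]` (default 1: boosted exactly one
#'   condition before it vanishes).
#' @param fold_ramp Number of condition steps over which a residue folds
#'   before vanishing (default 2).
#' @param proline_delta_bg_ppm Planted trans Cbeta-Cgamma difference
#'   (default 5 ppm).
#' @param minor_positions Residues emitting minor-state duplicate peaks
#'   (default 9, 10, 13, 14; also emits a minor-state duplicate for the
#'   first proline).
#' @param minor_offset_ppm Proton offset of minor-state duplicates.
#' @param i0 Reference intensity of the CPMG decays.
#' @param cpmg_delays_s CPMG delay schedule (default
#'   [default_cpmg_delays()]).
#' @return A list of class `ground_truth_config`.
#' @export
ground_truth_config <- function(n_res = 137L,
                                sequence = NULL,
                                prolines = c(12L, 38L, 67L),
                                nucleation = c(109L, 116L),
                                flexible = c(2L, 32L),
                                stage_plan = NULL,
                                elongation_rate = 12L,
                                dmso_fractions = c(1, 0.9, 0.85, 0.8, 0.7, 0.5),
                                temperature_c = 45,
                                field_mhz = 800,
                                helix_propensity = NULL,
                                helix_offset_ppm = 2.8,
                                shift_sigma_ppm = 0.2,
                                intensity_sigma_frac = 0.02,
                                j_sigma_hz = 0.3,
                                j_coil_hz = 7.0,
                                j_helix_hz = 4.0,
                                j_floor_hz = 3.0,
                                r2_base_s = 3.0,
                                r2_exchange_boost_s = 12.0,
                                boost_window = 1L,
                                fold_ramp = 2L,
                                proline_delta_bg_ppm = 5.0,
                                minor_positions = c(9L, 10L, 13L, 14L),
                                minor_offset_ppm = 0.05,
                                i0 = 100,
                                cpmg_delays_s = default_cpmg_delays()) {
  cfg <- as.list(environment())
  class(cfg) <- "ground_truth_config"
  cfg
}

# deterministic landmark sequence for the default fixture (synthetic; the
# real construct's sequence is not modelled, only its segment landmarks)
synthetic_fixture_sequence <- function(n_res = 137L,
                                       prolines = c(12L, 38L, 67L)) {
  base <- rep(c("A", "E", "L", "K", "S", "N", "D", "R", "I", "Q"),
              length.out = n_res)
  base[1] <- "M"
  if (n_res >= 2) base[2] <- "S"
  if (n_res >= 32) base[32] <- "F"     # aromatic: exercises the J correction
  if (n_res >= 109) base[109] <- "R"
  if (n_res >= 112) base[112] <- "E"
  if (n_res >= 115) base[115] <- "R"
  if (n_res >= 116) base[116] <- "M"
  base[prolines] <- "P"
  base
}

# the default staged-disappearance plan for the 137-residue fixture:
# elongation in both directions away from the nucleation segment
default_stage_plan <- function() {
  list(
    "1" = list(c(109L, 116L)),
    "2" = list(c(98L, 108L), c(117L, 121L)),
    "3" = list(c(69L, 97L), c(122L, 125L)),
    "4" = list(c(43L, 68L), c(126L, 137L)),
    "5" = list(c(39L, 42L)),
    "6" = list(c(33L, 38L))
  )
}

# radiating plan for custom nucleation geometries: stage grows with
# distance from the nucleation segment at `rate` residues per condition
radiating_stage_plan <- function(positions, nucleation, n_conditions,
                                 rate, flexible = NULL) {
  dist <- pmax(0L, pmax(nucleation[1] - positions, positions - nucleation[2]))
  stage <- 1 + ceiling(dist / rate)
  stage[stage > n_conditions] <- Inf
  if (!is.null(flexible)) {
    stage[positions >= flexible[1] & positions <= flexible[2]] <- Inf
  }
  stage
}

stage_vector_from_plan <- function(positions, plan, flexible = NULL) {
  stage <- rep(Inf, length(positions))
  for (s in names(plan)) {
    for (iv in plan[[s]]) {
      stage[positions >= iv[1] & positions <= iv[2]] <- as.numeric(s)
    }
  }
  if (!is.null(flexible)) {
    stage[positions >= flexible[1] & positions <= flexible[2]] <- Inf
  }
  stage
}

#' Build the planted ground truth of a synthetic titration study
#'
#' Deterministic for a fixed seed and configuration. Validates that the
#' nucleation segment does not touch a chain terminus and that the
#' incorporation stages are non-decreasing with distance from the
#' nucleation segment along each arm (the elongation-in-both-directions
#' model); the first residue (stage 0, never observable) is exempt.
#'
#' @param config A [ground_truth_config()].
#' @param seed Integer seed stored in the truth and used by
#'   [emit_observables()].
#' @return A list of class `ground_truth` with the sequence, condition
#'   ladder, per-residue `stage` and `propensity`, and the configuration.
#' @export
make_ground_truth <- function(config = ground_truth_config(), seed = 1L) {
  stopifnot(inherits(config, "ground_truth_config"))
  aa <- config$sequence %||%
    synthetic_fixture_sequence(config$n_res, config$prolines)
  seq <- protein_sequence(aa, name = "synthetic-titration-fixture")
  pos <- seq$positions
  nuc <- as.integer(config$nucleation)
  if (nuc[1] <= min(pos) || nuc[2] >= max(pos)) {
    stop("nucleation segment must not overlap a chain terminus", call. = FALSE)
  }
  plan <- config$stage_plan
  if (is.null(plan) && identical(nuc, c(109L, 116L)) &&
      length(pos) == 137L) {
    stage <- stage_vector_from_plan(pos, default_stage_plan(),
                                    flexible = config$flexible)
  } else if (is.null(plan)) {
    stage <- radiating_stage_plan(pos, nuc, length(config$dmso_fractions),
                                  config$elongation_rate,
                                  flexible = config$flexible)
  } else {
    stage <- stage_vector_from_plan(pos, plan, flexible = config$flexible)
  }
  stage[pos == min(pos)] <- 0  # free alpha-amine: never observable
  check_arm <- function(arm_stages) {
    s <- arm_stages[arm_stages > 0]  # ignore the unobservable first residue
    s[is.infinite(s)] <- .Machine$double.xmax  # Inf - Inf would be NaN
    if (any(diff(s) < 0)) {
      stop("incorporation stages must be non-decreasing with distance from the nucleation segment",
           call. = FALSE)
    }
  }
  check_arm(stage[pos < nuc[1]][order(pos[pos < nuc[1]], decreasing = TRUE)])
  check_arm(stage[pos > nuc[2]])
  prop <- config$helix_propensity
  if (is.null(prop)) {
    prop <- numeric(length(pos))
    prop[pos >= 41 & pos <= 121] <- 1
    prop[pos > 121] <- 0.7
  } else {
    prop <- rep_len(as.numeric(prop), length(pos))
  }
  prop[seq$aa == "P"] <- 0
  conditions <- condition_ladder(config$dmso_fractions,
                                 temperature_c = config$temperature_c,
                                 field_mhz = config$field_mhz)
  structure(list(seq = seq, conditions = conditions,
                 stage = setNames(stage, pos),
                 propensity = setNames(prop, pos),
                 nucleation = nuc, config = config,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d residues, nucleation [%d-%d], %d conditions, seed %d\n",
              length(x$seq), x$nucleation[1], x$nucleation[2],
              length(x$conditions), x$seed))
  invisible(x)
}

#' Per-residue folded fraction at one condition
#'
#' A residue at incorporation stage `s` folds over the `fold_ramp`
#' conditions preceding its disappearance:
#' `f = clamp((k - s + ramp) / ramp, 0, 1)` at condition index `k`.
#' Monotone non-increasing in DMSO fraction for every residue; residues
#' that never incorporate (stage `Inf`) stay at 0.
#'
#' @param truth A [make_ground_truth()] result.
#' @param condition_index Index into the ladder (1 = most denaturing).
#' @return Named numeric vector over residue positions.
#' @export
fold_fraction <- function(truth, condition_index) {
  stopifnot(inherits(truth, "ground_truth"))
  k <- as.numeric(condition_index)
  s <- truth$stage
  ramp <- as.numeric(truth$config$fold_ramp)
  f <- (k - s + ramp) / ramp
  f[is.infinite(s)] <- 0
  pmin(pmax(f, 0), 1)
}

# deterministic per-residue amide peak centres (stable across conditions)
peak_centres <- function(positions) {
  list(h = 7.8 + 0.8 * ((positions * 37) %% 100) / 100,
       n = 110 + 14 * ((positions * 61) %% 100) / 100)
}

#' Emit the full set of synthetic observables from a ground truth
#'
#' Generates, for every condition of the ladder: an assigned shift table
#' (amide H/N and Calpha for observable residues, Cbeta/Cgamma for
#' prolines, minor-state duplicates for the configured residues), a
#' resolved-doublet list (splitting shrinking from coil toward helix with
#' the folded fraction, omitted below the resolution floor), a CPMG
#' intensity series (monoexponential decays at the baseline R2 plus an
#' exchange boost for residues about to be incorporated), and the
#' ground-truth presence matrix. Deterministic for a fixed truth (the
#' seed stored in the truth drives all randomness).
#'
#' @param truth A [make_ground_truth()] result.
#' @return A list of class `synthetic_observables` with elements `truth`,
#'   `seq`, `conditions`, `shift_tables`, `doublets`, `relaxation`,
#'   `presence`.
#' @export
emit_observables <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  seq <- truth$seq
  pos <- seq$positions
  pro <- prolines(seq)
  ladder <- truth$conditions
  labels <- ladder_labels(ladder)
  K <- length(ladder)
  centres <- peak_centres(pos)
  rc <- default_random_coil_tables()
  set.seed(truth$seed)
  shift_tables <- list()
  doublets <- list()
  relaxation <- list()
  states <- matrix("absent", nrow = length(pos), ncol = K,
                   dimnames = list(pos, labels))
  minor_pro <- if (length(pro)) pro[1] else integer(0)
  for (k in seq_len(K)) {
    cond <- ladder[[k]]
    w <- solvent_weights(cond)
    f <- fold_fraction(truth, k)
    observable <- truth$stage > k & !(pos %in% pro)
    obs_pos <- pos[observable]
    obs_idx <- match(obs_pos, pos)
    # --- shift records -----------------------------------------------------
    aa <- seq$aa[obs_idx]
    baseline <- w[1] * as.numeric(rc$dmso[aa]) +
      w[2] * as.numeric(rc$aqueous[aa])
    ca <- baseline + cfg$helix_offset_ppm * truth$propensity[obs_idx] *
      f[obs_idx] + rnorm(length(obs_pos), 0, cfg$shift_sigma_ppm)
    h <- centres$h[obs_idx] + rnorm(length(obs_pos), 0, 0.01)
    n <- centres$n[obs_idx] + rnorm(length(obs_pos), 0, 0.05)
    rec <- rbind(
      data.frame(position = obs_pos, nucleus = "H", shift_ppm = h,
                 state = "major", stringsAsFactors = FALSE),
      data.frame(position = obs_pos, nucleus = "N", shift_ppm = n,
                 state = "major", stringsAsFactors = FALSE),
      data.frame(position = obs_pos, nucleus = "CA", shift_ppm = ca,
                 state = "major", stringsAsFactors = FALSE)
    )
    # minor-state duplicates (slow-exchange conformers) for the configured
    # residues while they remain observable
    minors <- intersect(cfg$minor_positions, obs_pos)
    if (length(minors)) {
      mi <- match(minors, obs_pos)
      rec <- rbind(rec,
        data.frame(position = minors, nucleus = "H",
                   shift_ppm = h[mi] + cfg$minor_offset_ppm,
                   state = "minor", stringsAsFactors = FALSE),
        data.frame(position = minors, nucleus = "N",
                   shift_ppm = n[mi] + 10 * cfg$minor_offset_ppm,
                   state = "minor", stringsAsFactors = FALSE))
    }
    # proline Cb/Cg: the trans signature is planted as an exact pairwise
    # difference (the classifier consumes only the difference), with the
    # absolute Cb position carrying the shift noise
    if (length(pro)) {
      cb <- 31.8 + rnorm(length(pro), 0, cfg$shift_sigma_ppm)
      rec <- rbind(rec,
        data.frame(position = pro, nucleus = "CB", shift_ppm = cb,
                   state = "major", stringsAsFactors = FALSE),
        data.frame(position = pro, nucleus = "CG",
                   shift_ppm = cb - cfg$proline_delta_bg_ppm,
                   state = "major", stringsAsFactors = FALSE))
      if (length(minor_pro)) {
        cbm <- 31.8 + rnorm(1, 0, cfg$shift_sigma_ppm) + 0.3
        rec <- rbind(rec,
          data.frame(position = minor_pro, nucleus = "CB", shift_ppm = cbm,
                     state = "minor", stringsAsFactors = FALSE),
          data.frame(position = minor_pro, nucleus = "CG",
                     shift_ppm = cbm - cfg$proline_delta_bg_ppm,
                     state = "minor", stringsAsFactors = FALSE))
      }
    }
    shift_tables[[labels[k]]] <- shift_table(cond, rec, seq = seq)
    # --- doublets ----------------------------------------------------------
    j_true <- cfg$j_coil_hz - (cfg$j_coil_hz - cfg$j_helix_hz) *
      truth$propensity[obs_idx] * f[obs_idx]
    resolved <- j_true >= cfg$j_floor_hz
    if (any(resolved)) {
      j_noisy <- pmax(0, j_true[resolved] +
                        rnorm(sum(resolved), 0, cfg$j_sigma_hz))
      split_ppm <- j_noisy / cond$field_mhz
      doublets[[labels[k]]] <- doublet_table(cond, data.frame(
        position = obs_pos[resolved],
        h_ppm_low = h[resolved] - split_ppm / 2,
        h_ppm_high = h[resolved] + split_ppm / 2,
        n_ppm = n[resolved], stringsAsFactors = FALSE))
    }
    # --- CPMG decays -------------------------------------------------------
    boosted <- truth$stage[obs_idx] > k &
      truth$stage[obs_idx] <= k + cfg$boost_window
    r2_true <- cfg$r2_base_s + ifelse(boosted, cfg$r2_exchange_boost_s, 0)
    t <- cfg$cpmg_delays_s
    decays <- outer(r2_true, t, function(r, tt) cfg$i0 * exp(-r * tt))
    noise <- matrix(rnorm(length(decays), 0, cfg$intensity_sigma_frac * cfg$i0),
                    nrow = nrow(decays))
    intens <- decays + noise
    rownames(intens) <- obs_pos
    errs <- matrix(cfg$intensity_sigma_frac * cfg$i0,
                   nrow = nrow(intens), ncol = ncol(intens),
                   dimnames = dimnames(intens))
    relaxation[[labels[k]]] <- relaxation_series(cond, t, intens, errs)
    # --- presence ----------------------------------------------------------
    st <- rep("absent", length(pos))
    st[observable] <- "present"
    st[observable & pos %in% cfg$minor_positions] <- "minor_duplicate"
    states[, k] <- st
  }
  presence <- presence_matrix(ladder, states, proline_mask = pro)
  structure(list(truth = truth, seq = seq, conditions = ladder,
                 shift_tables = shift_tables, doublets = doublets,
                 relaxation = relaxation, presence = presence),
            class = "synthetic_observables")
}

#' @export
print.synthetic_observables <- function(x, ...) {
  cat(sprintf("<synthetic_observables> %d conditions, %d residues, seed %d\n",
              length(x$conditions), length(x$seq), x$truth$seed))
  invisible(x)
}

#' Write a set of observables to a directory of plain-text tables
#'
#' Writes `sequence.fasta`, `conditions.tsv`, `shifts.tsv`, `doublets.tsv`,
#' `relaxation.tsv` and `presence.tsv`.
#'
#' @param obs A [emit_observables()] result (or any list with the same
#'   elements).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observables <- function(obs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_sequence(obs$seq, file.path(dir, "sequence.fasta"))
  write_tsv_raw(conditions_table(obs$conditions),
                file.path(dir, "conditions.tsv"))
  write_shift_tables(obs$shift_tables, file.path(dir, "shifts.tsv"))
  if (length(obs$doublets)) {
    write_doublet_tables(obs$doublets, file.path(dir, "doublets.tsv"))
  }
  write_relaxation_tables(obs$relaxation, file.path(dir, "relaxation.tsv"))
  write_presence_table(obs$presence, file.path(dir, "presence.tsv"))
  invisible(dir)
}

#' Read a directory of observable tables written by [write_observables()]
#'
#' @param dir Directory path.
#' @return A list with `seq`, `conditions`, `shift_tables`, `doublets`,
#'   `relaxation`, `presence`.
#' @export
read_observables <- function(dir) {
  seq <- read_fasta_sequence(file.path(dir, "sequence.fasta"))
  ladder <- ladder_from_table(
    read_checked_tsv(file.path(dir, "conditions.tsv"),
                     numeric_cols = c("dmso_fraction", "temperature_c",
                                      "field_mhz"),
                     character_cols = "label"))
  doublet_path <- file.path(dir, "doublets.tsv")
  list(
    seq = seq,
    conditions = ladder,
    shift_tables = read_shift_tables(file.path(dir, "shifts.tsv"), ladder, seq),
    doublets = if (file.exists(doublet_path))
      read_doublet_tables(doublet_path, ladder, seq) else list(),
    relaxation = read_relaxation_tables(file.path(dir, "relaxation.tsv"),
                                        ladder, seq),
    presence = read_presence_table(file.path(dir, "presence.tsv"), ladder,
                                   prolines(seq))
  )
}
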