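# Seeded synthetic-data generators. Every generator consumes an explicit
# seed, emits a machine-readable truth table alongside its data, and is
# parameterized by named presets that encode the printed effect sizes of the
# study conditions (fold-changes, turnover means/SDs, resting pH_i, cAMP
# trace anchors, motile fractions). Noise families: lognormal for plates,
# Gaussian for traces and titrations, Poisson for images.

#' Named fixture presets
#'
#' Immutable parameter sets used by the generators. Fold-change presets
#' give the pH 7 -> pH 8 activation ratio per construct and metal; the
#' turnover preset gives the per-pH means, SDs and sample sizes of the
#' purified-enzyme MgATP measurements; the remaining presets parameterize
#' the resting-pH titration, the bulk cAMP trace, and the motility movies.
#'
#' @param name Preset name; with no argument, the list of all presets.
#' @return The preset (a list), or the named list of all presets.
#' @export
#' @examples
#' fixture_preset("apsac_fl_mg")$ratio
fixture_preset <- function(name = NULL) {
  fold <- function(construct, metal, ratio)
    list(type = "fold_plate", construct = construct, metal = metal,
         ratio = ratio, base_mean = 0.1, cv = 0.10, n = 3)
  presets <- list(
    apsac_fl_mg = fold("ApsAC_fl", "Mg", 5.4),
    apsac_fl_mn = fold("ApsAC_fl", "Mn", 4.3),
    apsact_mg = fold("ApsAC_t", "Mg", 1.2),
    apsact_mn = fold("ApsAC_t", "Mn", 2.5),
    sssact_mg = fold("SssAC_t", "Mg", 1.4),
    sssact_mn = fold("SssAC_t", "Mn", 3.0),
    rnsact_hco3_mg = fold("RnsAC_t", "Mg", 2.0),
    rnsact_ph_mg = fold("RnsAC_t", "Mg", 1.6),
    rnsact_ph_mn = fold("RnsAC_t", "Mn", 1.3),
    apsact_mg_turnover = list(
      type = "turnover_plate", metal = "Mg",
      ph = c(6.7, 7.0, 7.2, 8.0),
      k_mean = c(0.035, 0.070, 0.035, 0.106),
      k_sd = c(0.013, 0.026, 0.013, 0.041),
      n = c(26L, 20L, 17L, 20L),
      time_s = 600, enzyme_pmol = 0.01),
    resting_phi = list(
      type = "nullpoint", ph_i = 6.84, slope = 1,
      noise_sd = 0.017, probes = seq(6.59, 7.09, by = 0.1),
      replicates = 3L),
    camp_trace = list(
      type = "trace", baseline = 0.23, plateau = 15.1, t_half = 50,
      noise_sd = 0.5, times = seq(0, 200, by = 2)),
    arbacia_asw_motility = list(
      type = "movie", n_movies = 3L, n_cells = c(247L, 247L, 246L),
      motile_fraction = 0.875, fps = 25, n_frames = 26L,
      dim = c(320L, 320L), speed_px = 2.5),
    salmo_uncage = list(
      # 429 cells / 412 responders pooled over several photorelease
      # experiments; emulated as three fields of view at realistic density
      type = "movie", n_movies = 3L, n_cells = c(143L, 143L, 143L),
      n_responders = c(137L, 137L, 138L), fps = 40, n_frames = 30L,
      dim = c(400L, 400L), speed_px = 3,
      flash_frame = 5L, onset_after_flash = 4L),
    mammal_kr = list(
      type = "sequences", n = 100L, label = "K/R", group = "mammal",
      sub_rate = 0.05, indel_rate = 0.01))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset: ", name, call. = FALSE)
  c(presets[[name]], list(name = name))
}

# mean/sd -> lognormal draws with exactly that mean and (approx.) sd;
# cv = 0 returns the mean itself.
rlnorm_mean_sd <- function(n, mean, sd) {
  stopifnot(all(mean > 0))
  if (all(sd == 0)) return(rep(mean, length.out = n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate ortholog sequences with planted bicarbonate-site genotypes
#'
#' Derives `n` query sequences from the reference by seeded point
#' substitutions and short indels, then forces the residues at the positions
#' homologous to K95 and R176 to the preset genotype label. The emitted
#' truth table records where the planted sites ended up in each query.
#'
#' @param preset A `fixture_preset()` of type `"sequences"`, or a list with
#'   `n`, `label` (e.g. `"K/N"`), `group`, `sub_rate`, `indel_rate`.
#' @param reference Reference [protein_record()] (default the packaged
#'   synthetic human-numbered reference).
#' @param sites [hs_sac_sites()] giving the reference positions to plant.
#' @param seed Integer seed (mandatory).
#' @return A list with `records` (list of [protein_record()]) and `truth`
#'   (data frame: id, group, label, q95, q176).
#' @export
gen_sequences <- function(preset = fixture_preset("mammal_kr"),
                          reference = hs_sac_reference(),
                          sites = hs_sac_sites(), seed) {
  lab <- strsplit(preset$label, "/")[[1]]
  if (length(lab) != 2 || !all(lab %in% AA_ALPHABET))
    stop("genotype label must be two amino-acid letters joined by '/'",
         call. = FALSE)
  p95 <- sites$bicarbonate[["K95"]]; p176 <- sites$bicarbonate[["R176"]]
  refl <- strsplit(reference$residues, "")[[1]]
  nref <- length(refl)
  aa20 <- AA_ALPHABET[AA_ALPHABET != "X"]
  local_seed(seed, {
    recs <- vector("list", preset$n)
    truth <- vector("list", preset$n)
    for (s in seq_len(preset$n)) {
      letters <- refl
      protected <- c(p95, p176)
      subs <- which(runif(nref) < preset$sub_rate)
      subs <- setdiff(subs, protected)
      letters[subs] <- vapply(letters[subs], function(l)
        sample(setdiff(aa20, l), 1), character(1))
      del <- which(runif(nref) < preset$indel_rate / 2)
      del <- setdiff(del, protected)
      ins_at <- which(runif(nref) < preset$indel_rate / 2)
      ins_seq <- lapply(ins_at, function(i)
        sample(aa20, sample(1:3, 1), replace = TRUE))
      pieces <- as.list(letters)
      pieces[del] <- list(character(0))
      for (k in seq_along(ins_at))
        pieces[[ins_at[k]]] <- c(pieces[[ins_at[k]]], ins_seq[[k]])
      out <- unlist(pieces)
      # query position of each surviving reference position
      lens <- lengths(pieces)
      ends <- cumsum(lens)
      qpos <- function(rp) if (rp %in% del) NA_integer_ else
        ends[rp] - lens[rp] + 1L
      q95 <- qpos(p95); q176 <- qpos(p176)
      out[q95] <- lab[1]; out[q176] <- lab[2]
      id <- sprintf("%s_%03d", preset$group, s)
      recs[[s]] <- protein_record(id, paste(out, collapse = ""),
                                  species = sprintf("synthetic %s %d",
                                                    preset$group, s),
                                  group = preset$group)
      truth[[s]] <- data.frame(id = id, group = preset$group,
                               label = preset$label, q95 = q95,
                               q176 = q176)
    }
    list(records = recs, truth = do.call(rbind, truth))
  })
}

#' Generate a fold-change assay plate
#'
#' Two conditions (pH 7 and pH 8) at the preset mean ratio, lognormal
#' multiplicative noise at the preset CV, `n` replicates each.
#'
#' @param preset A fold-change `fixture_preset()` (e.g. `"apsac_fl_mg"`).
#' @param seed Integer seed.
#' @return A data frame with `condition`, `construct`, `metal`,
#'   `replicate`, `value` (cAMP pmol), plus the generating truth as
#'   attribute `"truth"`.
#' @export
gen_plate <- function(preset = fixture_preset("apsac_fl_mg"), seed) {
  stopifnot(preset$type == "fold_plate")
  if (preset$base_mean <= 0) stop("nonpositive mean", call. = FALSE)
  means <- c(pH7 = preset$base_mean,
             pH8 = preset$base_mean * preset$ratio)
  local_seed(seed, {
    rows <- lapply(names(means), function(cond) {
      data.frame(condition = cond, construct = preset$construct,
                 metal = preset$metal, replicate = seq_len(preset$n),
                 value = rlnorm_mean_sd(preset$n, means[[cond]],
                                        preset$cv * means[[cond]]))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(ratio = preset$ratio, means = means)
    out
  })
}

#' Generate a per-pH turnover assay plate
#'
#' Draws per-replicate turnover numbers around the preset per-pH means
#' (lognormal, preset SDs) and converts them to the cAMP amounts a plate
#' would show at the preset reaction time and enzyme amount, so the
#' downstream [turnover()] pipeline can be exercised end to end.
#'
#' @param preset The `"apsact_mg_turnover"` `fixture_preset()`.
#' @param seed Integer seed.
#' @return A data frame with `condition` (pH as character), `ph`,
#'   `replicate`, `camp_pmol`, `time_s`, `enzyme_pmol`; the generating
#'   truth (`k_mean`, `k_sd` per pH) is attached as attribute `"truth"`.
#' @export
gen_turnover_plate <- function(preset = fixture_preset("apsact_mg_turnover"),
                               seed) {
  stopifnot(preset$type == "turnover_plate")
  local_seed(seed, {
    rows <- lapply(seq_along(preset$ph), function(i) {
      k <- rlnorm_mean_sd(preset$n[i], preset$k_mean[i], preset$k_sd[i])
      data.frame(condition = sprintf("pH%.1f", preset$ph[i]),
                 ph = preset$ph[i], replicate = seq_len(preset$n[i]),
                 camp_pmol = k * preset$time_s * preset$enzyme_pmol,
                 time_s = preset$time_s,
                 enzyme_pmol = preset$enzyme_pmol)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(ph = preset$ph,
                                     k_mean = preset$k_mean,
                                     k_sd = preset$k_sd, n = preset$n)
    out
  })
}

#' Generate a bulk cAMP time course
#'
#' Baseline-to-plateau exponential
#' `baseline + (plateau - baseline) * (1 - 2^(-t / t_half))` with seeded
#' Gaussian noise, in pmol per 1e8 cells.
#'
#' @param preset The `"camp_trace"` `fixture_preset()` (baseline 0.23,
#'   plateau 15.1, half-time 50 s by default).
#' @param seed Integer seed.
#' @return A data frame with `time_s` and `camp_pmol`; truth attached as
#'   attribute `"truth"`.
#' @export
gen_camp_trace <- function(preset = fixture_preset("camp_trace"), seed) {
  stopifnot(preset$type == "trace")
  if (preset$t_half <= 0) stop("t_half must be positive", call. = FALSE)
  t <- preset$times
  clean <- preset$baseline +
    (preset$plateau - preset$baseline) * (1 - 2^(-t / preset$t_half))
  local_seed(seed, {
    out <- data.frame(time_s = t,
                      camp_pmol = clean + rnorm(length(t), 0,
                                                preset$noise_sd))
    attr(out, "truth") <- preset[c("baseline", "plateau", "t_half")]
    out
  })
}

#' Generate a null-point pH titration
#'
#' The null-point (pseudo-null-point) method estimates resting
#' intracellular pH as the external pH at which a permeabilization-induced
#' fluorescence change is zero: `dF = slope * (pH_o - pH_i) + noise`.
#'
#' @param preset The `"resting_phi"` `fixture_preset()`.
#' @param seed Integer seed.
#' @return A data frame with `replicate`, `ph_o`, `dF`; truth pH_i as
#'   attribute `"truth"`.
#' @export
gen_nullpoint <- function(preset = fixture_preset("resting_phi"), seed) {
  stopifnot(preset$type == "nullpoint")
  local_seed(seed, {
    rows <- lapply(seq_len(preset$replicates), function(r) {
      data.frame(replicate = r, ph_o = preset$probes,
                 dF = preset$slope * (preset$probes - preset$ph_i) +
                   rnorm(length(preset$probes), 0, preset$noise_sd))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- preset$ph_i
    out
  })
}

#' Estimate resting pH from a null-point titration
#'
#' Linear zero-crossing interpolation between the first pair of probe
#' points whose responses bracket zero.
#'
#' @param ph_o Probe external pH values (increasing).
#' @param dF Fluorescence responses.
#' @return A list with `ph_i` (`NA` if no sign change) and `bracketed`.
#' @export
#' @examples
#' estimate_nullpoint(c(6.6, 7.0), c(-0.2, 0.2))$ph_i  # 6.8
estimate_nullpoint <- function(ph_o, dF) {
  o <- order(ph_o); ph_o <- ph_o[o]; dF <- dF[o]
  cross <- which(dF[-length(dF)] * dF[-1] <= 0 &
                   (dF[-length(dF)] != 0 | dF[-1] != 0))
  if (!length(cross)) return(list(ph_i = NA_real_, bracketed = FALSE))
  i <- cross[1]
  ph <- ph_o[i] + (0 - dF[i]) * (ph_o[i + 1] - ph_o[i]) /
    (dF[i + 1] - dF[i])
  list(ph_i = ph, bracketed = TRUE)
}

#' Generate a synthetic dark-field sperm movie
#'
#' Point-like cells rendered as Gaussian blobs on a constant background
#' with Poisson shot noise. Motile cells move by a persistent random walk;
#' static cells jitter far below the motile threshold. For photorelease
#' presets, all cells are static until the flash and the preset number of
#' responders starts moving a fixed number of frames after it.
#'
#' @param preset A `"movie"` `fixture_preset()` (one movie's worth:
#'   `n_cells` may be a vector in the preset, pass `movie_index` to pick).
#' @param seed Integer seed.
#' @param movie_index Which movie of the preset to generate.
#' @param blob_sigma,amplitude,background Rendering parameters (px,
#'   photons).
#' @return A list with `stack` ([movie_stack()]) and `truth` (data frame:
#'   cell, x0, y0, motile, onset_frame).
#' @export
gen_movie <- function(preset = fixture_preset("arbacia_asw_motility"),
                      seed, movie_index = 1L, blob_sigma = 1.2,
                      amplitude = 150, background = 10) {
  stopifnot(preset$type == "movie")
  n <- if (length(preset$n_cells) > 1) preset$n_cells[movie_index]
       else preset$n_cells
  H <- preset$dim[1]; W <- preset$dim[2]
  if (n * (6 * blob_sigma)^2 > 0.5 * H * W)
    stop("cell density beyond packing limit", call. = FALSE)
  nf <- preset$n_frames
  flash <- preset$flash_frame %||% NA_integer_
  local_seed(seed + movie_index, {
    margin <- 8
    x <- runif(n, margin, H - margin)
    y <- runif(n, margin, W - margin)
    if (!is.null(preset$n_responders)) {
      nr <- if (length(preset$n_responders) > 1)
        preset$n_responders[movie_index] else preset$n_responders
      movers <- seq_len(n) %in% sample.int(n, nr)
      onset <- ifelse(movers, flash + preset$onset_after_flash, NA)
    } else {
      n_mot <- round(n * preset$motile_fraction)
      movers <- seq_len(n) %in% sample.int(n, n_mot)
      onset <- ifelse(movers, 2L, NA)
    }
    theta <- runif(n, 0, 2 * pi)
    frames <- array(0, dim = c(H, W, nf))
    truth <- data.frame(cell = seq_len(n), x0 = x, y0 = y,
                        motile = movers, onset_frame = onset)
    half <- ceiling(4 * blob_sigma)
    for (f in seq_len(nf)) {
      if (f > 1) {
        act <- movers & !is.na(onset) & f >= onset
        theta[act] <- theta[act] + rnorm(sum(act), 0, 0.3)
        x[act] <- x[act] + preset$speed_px * cos(theta[act])
        y[act] <- y[act] + preset$speed_px * sin(theta[act])
        # reflect at borders
        x <- pmin(pmax(x, margin / 2), H - margin / 2)
        y <- pmin(pmax(y, margin / 2), W - margin / 2)
        x[!act] <- x[!act] + rnorm(sum(!act), 0, 0.05)
        y[!act] <- y[!act] + rnorm(sum(!act), 0, 0.05)
      }
      img <- matrix(background, H, W)
      for (ci in seq_len(n)) {
        xi <- round(x[ci]); yi <- round(y[ci])
        rr <- max(1, xi - half):min(H, xi + half)
        cc <- max(1, yi - half):min(W, yi + half)
        g <- amplitude *
          exp(-outer((rr - x[ci])^2, (cc - y[ci])^2, "+") /
                (2 * blob_sigma^2))
        img[rr, cc] <- img[rr, cc] + g
      }
      frames[, , f] <- matrix(rpois(H * W, img), H, W)
    }
    list(stack = movie_stack(frames, preset$fps, flash),
         truth = truth)
  })
}
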