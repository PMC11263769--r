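# End-to-end orchestration of the three correction methods: per-case
# acquisition simulation, training-pair construction, cross-validated
# training, and AC-image production.

method_kinds <- c("indirect", "direct", "direct_hrc")

#' Acquisition parameters for the simulated scanner
#'
#' @param psf scanner [psf_model()].
#' @param n_angles projection angles per acquisition.
#' @param total_counts expected total counts (0 = noise-free native scale).
#' @param poisson draw Poisson noise.
#' @param thresholds [mu_map_thresholds()] used for the ground-truth CTAC
#'   mu-map.
#' @param recon reconstruction used for the non-AC and CTAC images
#'   (`"fbp"` or `"osem"`).
#' @param hrc [hrc_config()] for the CTAC+HRC reference.
#' @param iterations,subsets OSEM settings when `recon = "osem"`.
#' @export
acquisition_params <- function(psf = psf_model(5), n_angles = 180,
                               total_counts = 5e5, poisson = TRUE,
                               thresholds = mu_map_thresholds(),
                               recon = "fbp", hrc = hrc_config(psf = psf),
                               iterations = 3, subsets = 15) {
  structure(list(psf = psf, n_angles = as.integer(n_angles),
                 total_counts = total_counts, poisson = poisson,
                 thresholds = thresholds, recon = recon, hrc = hrc,
                 iterations = iterations, subsets = subsets),
            class = "acquisition_params")
}

case_seed <- function(case_id, seed) {
  derive_seed(seed, sum(utf8ToInt(case_id)))
}

#' Simulate one case's PET acquisition and reference images
#'
#' Produces, for a phantom case: the emission sinogram (seeded Poisson),
#' the true-mu attenuation factors, the uncorrected (non-AC)
#' reconstruction, the CT-based attenuation-corrected (CTAC)
#' reconstruction, and the Richardson-Lucy corrected CTAC+HRC reference.
#'
#' @param case a `phantom_case`.
#' @param acq an [acquisition_params()].
#' @param seed global seed; the per-case seed is derived from it and the
#'   case id.
#' @export
simulate_case_acquisition <- function(case, acq = acquisition_params(),
                                      seed = 1) {
  stopifnot(inherits(case, "phantom_case"))
  px <- case$pixel_size_mm
  n <- nrow(case$ct_hu)
  geometry <- default_geometry(n, px, acq$n_angles)
  mu_true <- hu_to_mu(case$ct_hu, acq$thresholds, px)
  em <- simulate_emission(case$activity, mu_true, acq$psf, geometry,
                          total_counts = acq$total_counts,
                          seed = case_seed(case$case_id, seed),
                          pixel_size_mm = px, poisson = acq$poisson)
  att <- attenuation_factors(mu_true, geometry)
  non_ac <- reconstruct_fbp(em, geometry, n, px)
  ctac <- ctac_correct(em, att, geometry, n, recon = acq$recon,
                       pixel_size_mm = px, iterations = acq$iterations,
                       subsets = acq$subsets)
  hrc_ref <- make_hrc_reference(ctac, acq$hrc, px)
  list(case_id = case$case_id, geometry = geometry, pixel_size_mm = px,
       emission = em, att = att, mu_true = mu_true,
       non_ac = non_ac, ctac = ctac, hrc_ref = hrc_ref)
}

#' Build training pairs for a correction method
#'
#' For each case the acquisition is simulated once under a fixed per-case
#' seed; inputs and targets are normalized to the display scale and
#' expanded 32-fold (rotations x translations x flip, applied identically
#' to input and target). Pairings per method: indirect trains MRI ->
#' windowed CT; direct trains non-AC -> CTAC; direct+HRC trains non-AC ->
#' CTAC+HRC.
#'
#' @param cohort list of `phantom_case` objects.
#' @param method one of `"indirect"`, `"direct"`, `"direct_hrc"`.
#' @param acq an [acquisition_params()].
#' @param seed global seed.
#' @param augment expand each pair 32-fold (default TRUE).
#' @param spec an [augmentation_spec()].
#' @return list with one entry per case: `case_id`, original `input` and
#'   `target` (display scale), their normalization records, the augmented
#'   pair lists, and the simulated `acquisition`.
#' @export
make_training_pairs <- function(cohort, method = method_kinds,
                                acq = acquisition_params(), seed = 1,
                                augment = TRUE, spec = augmentation_spec()) {
  method <- match.arg(method)
  if (!length(cohort)) stop("cohort must be nonempty", call. = FALSE)
  lapply(cohort, function(case) {
    acqr <- simulate_case_acquisition(case, acq, seed)
    if (method == "indirect") {
      nin <- normalize_counts(case$mri_t1)
      input <- nin$normalized; rec_in <- nin$record
      target <- window_ct(case$ct_hu)
      rec_tg <- structure(list(x_min = -1000, x_max = 1500),
                          class = "normalization_record")
    } else {
      nin <- normalize_counts(acqr$non_ac)
      ref <- if (method == "direct") acqr$ctac else acqr$hrc_ref
      ntg <- normalize_counts(ref)
      input <- nin$normalized; rec_in <- nin$record
      target <- ntg$normalized; rec_tg <- ntg$record
    }
    out <- list(case_id = case$case_id, method = method,
                input = input, target = target,
                record_input = rec_in, record_target = rec_tg,
                acquisition = acqr)
    if (augment) {
      out$aug_inputs <- augment32(input, spec)
      out$aug_targets <- augment32(target, spec)
    }
    out
  })
}

#' Apply the indirect method to one case
#'
#' Predicts a synthetic CT from the MRI, inverts the CT display window to
#' HU, segments it into a three-class 511-keV mu-map, and performs
#' CT-based attenuation correction of the emission data with the resulting
#' factors. `sct_model` may be a trained `petac_unet` or any function
#' mapping the normalized MRI to a windowed CT display image (oracle
#' substitution).
#'
#' @param mri MRI matrix (display scale).
#' @param non_ac_emission emission [sinogram()].
#' @param sct_model trained model or oracle function.
#' @param geometry [scan_geometry()] of the emission data.
#' @param thresholds [mu_map_thresholds()].
#' @param shape reconstruction side length.
#' @param pixel_size_mm pixel size.
#' @param reference_ac optional CTAC reference for evaluation.
#' @param case_id identifier carried into the result.
#' @param recon `"fbp"` or `"osem"`.
#' @return a case-result list with `predicted_ac`, `reference_ac` and
#'   intermediates (`sct_hu`, `mu_map`).
#' @export
run_indirect <- function(mri, non_ac_emission, sct_model, geometry,
                         thresholds = mu_map_thresholds(), shape = nrow(mri),
                         pixel_size_mm = 1, reference_ac = NULL,
                         case_id = "", recon = "fbp") {
  nin <- normalize_counts(mri)
  sct_disp <- unet_predict(sct_model, nin$normalized)
  sct_hu <- window_ct_inverse(sct_disp)
  mu <- hu_to_mu(sct_hu, thresholds, pixel_size_mm)
  att <- attenuation_factors(mu, geometry)
  predicted <- ctac_correct(non_ac_emission, att, geometry, shape,
                            recon = recon, pixel_size_mm = pixel_size_mm)
  list(case_id = case_id, method = "indirect", predicted_ac = predicted,
       reference_ac = reference_ac,
       intermediates = list(sct_hu = sct_hu, mu_map = mu))
}

#' Apply the direct method to one case
#'
#' One forward pass: the non-AC image is normalized, translated by the
#' model, and mapped back to native units. With no target-side record
#' available at inference, the input's own record is used for the inverse
#' mapping (evaluation rescales to the reference maximum, so the global
#' scale does not affect the metrics).
#'
#' @param non_ac_image uncorrected reconstruction (native units).
#' @param model trained `petac_unet` (or function, e.g. identity baseline).
#' @param record optional `normalization_record` for the inverse mapping.
#' @param reference_ac optional reference image for evaluation.
#' @param case_id identifier.
#' @param method result label (`"direct"` or `"direct_hrc"`).
#' @export
run_direct <- function(non_ac_image, model, record = NULL,
                       reference_ac = NULL, case_id = "", method = "direct") {
  nin <- normalize_counts(non_ac_image)
  pred_disp <- unet_predict(model, nin$normalized)
  rec <- if (is.null(record)) nin$record else record
  list(case_id = case_id, method = method,
       predicted_ac = denormalize(pred_disp, rec),
       reference_ac = reference_ac, intermediates = NULL)
}

#' Apply the direct+HRC method to one case
#'
#' Identical single forward pass to [run_direct()] — no deconvolution at
#' inference; the resolution correction lives in the training targets. The
#' reference is the CTAC+HRC image.
#'
#' @inheritParams run_direct
#' @export
run_direct_hrc <- function(non_ac_image, model, record = NULL,
                           reference_ac = NULL, case_id = "") {
  run_direct(non_ac_image, model, record, reference_ac, case_id,
             method = "direct_hrc")
}

#' Cross-validated training and out-of-fold prediction
#'
#' Assigns cases to folds (by case, never by augmented slice), trains one
#' model per fold on the augmented slices of the remaining cases, and
#' predicts each held-out case from its un-augmented original input.
#' Returns exactly one prediction per case, each from a model that never
#' saw any augmented copy of that case.
#'
#' @param cohort list of `phantom_case` objects.
#' @param method `"indirect"`, `"direct"` or `"direct_hrc"`.
#' @param acq an [acquisition_params()].
#' @param net a [unet_config()].
#' @param opt an [optimizer_config()].
#' @param tcfg a [train_config()] with `k_folds` set (protocol defaults: 6
#'   for indirect, 7 for direct, 10 for direct+HRC).
#' @param seed global seed (phantom acquisition, fold split, model
#'   initialization).
#' @param pairs optional precomputed [make_training_pairs()] output.
#' @return list with `results` (case results in cohort order), `folds`
#'   (the [kfold_split()] assignment), `provenance` (per-fold training
#'   case ids) and `loss_curves` (per fold).
#' @export
cross_validate <- function(cohort, method = method_kinds,
                           acq = acquisition_params(), net = unet_config(),
                           opt = optimizer_config(), tcfg, seed = 1,
                           pairs = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(tcfg, "train_config"))
  k <- tcfg$k_folds
  if (is.null(k))
    k <- switch(method, indirect = 6L, direct = 7L, direct_hrc = 10L)
  if (is.null(pairs))
    pairs <- make_training_pairs(cohort, method, acq, seed)
  ids <- vapply(pairs, `[[`, character(1), "case_id")
  folds <- kfold_split(ids, k, seed)
  results <- vector("list", length(pairs))
  names(results) <- ids
  provenance <- vector("list", k)
  loss_curves <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- ids[folds != f]
    test_ids <- ids[folds == f]
    provenance[[f]] <- train_ids
    tr <- pairs[match(train_ids, ids)]
    inputs <- unlist(lapply(tr, `[[`, "aug_inputs"), recursive = FALSE)
    targets <- unlist(lapply(tr, `[[`, "aug_targets"), recursive = FALSE)
    model <- build_unet(net, seed = derive_seed(seed, 7000 + f))
    model <- unet_train(model, inputs, targets, opt, tcfg)
    loss_curves[[f]] <- model$loss_curve
    for (id in test_ids) {
      e <- pairs[[match(id, ids)]]
      results[[id]] <- predict_case(e, model, method)
    }
  }
  list(results = unname(results[ids]), folds = folds,
       provenance = provenance, loss_curves = loss_curves)
}

# Out-of-fold prediction of one case entry with a trained model.
predict_case <- function(entry, model, method) {
  acqr <- entry$acquisition
  if (method == "indirect") {
    # entry$input is the normalized MRI; reconstruct with the predicted
    # SCT-derived mu-map and score against the CTAC reference
    res <- run_indirect(entry$input, acqr$emission, model, acqr$geometry,
                        shape = nrow(entry$input),
                        pixel_size_mm = acqr$pixel_size_mm,
                        reference_ac = acqr$ctac, case_id = entry$case_id)
  } else {
    ref <- if (method == "direct") acqr$ctac else acqr$hrc_ref
    res <- run_direct(acqr$non_ac, model, reference_ac = ref,
                      case_id = entry$case_id, method = method)
  }
  res
}
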