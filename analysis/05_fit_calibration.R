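#!/usr/bin/env Rscript
# Stage 5 — height calibration.
#
# Splits the kept footprint pairs 70/30 by height category, computes the
# per-category weights (1 / (n * 6)) on the training set, fits the four
# candidate regressions of RH98 on the footprint max DEM value (linear,
# quadratic, power, square-root linear), selects the best by RMSE, applies
# it to the mangrove-only DEM and validates on the 30% hold-out.
#
# Finds: prints the selected form with its coefficients and hold-out
# metrics; writes the model JSON, weight table and residual bins.

suppressPackageStartupMessages(library(mangroveheight))

scene <- generate_scene(scene_config(seed = 42L))
res <- run_pipeline(scene, seed = 1L)

write.csv(res$weights, "results/05_category_weights.csv", row.names = FALSE)
write_model_json(res$model, "results/05_calibration_model.json",
                 extra = list(split_seed = 1, train_n = nrow(res$split$train)))
write.csv(res$validation$residual_bins, "results/05_residual_bins.csv",
          row.names = FALSE)
cand <- do.call(rbind, lapply(names(res$models), function(f) {
  m <- res$models[[f]]$metrics
  data.frame(form = f, corr = m$corr, mae = m$mae, rmse = m$rmse,
             bias = m$bias)
}))
write.csv(cand, "results/05_candidate_models.csv", row.names = FALSE)
write_raster_txt(res$height_map, "scratch/05_height_map.txt")

v <- res$validation$metrics
message(sprintf("selected %s: %s", res$model$form,
                paste(sprintf("%s=%.4f", names(res$model$coef),
                              res$model$coef), collapse = " ")))
message(sprintf("hold-out (n=%d): CORR %.3f  MAE %.2f m  RMSE %.2f m  bias %.2f m",
                v$n, v$corr, v$mae, v$rmse, v$bias))
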