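# Schedule, training loop, determinism, checkpoint/resume, ablations,
# evaluation and prediction plumbing.

test_that("the learning-rate schedule hits its anchor points", {
  cfg <- mfel_config(epochs = 150, warmup_epochs = 5, working_size = 64)
  expect_equal(lr_at(0, cfg), 1e-5)                         # ramp start
  expect_equal(lr_at(5, cfg), 1e-3)                         # ramp end = cosine start
  expect_equal(lr_at(149, cfg), 1e-5, tolerance = 1e-12)    # cosine end
  # cosine midpoint: t = 0.5 -> (lr_init + lr_final) / 2
  mid <- 5 + (149 - 5) / 2
  expect_equal(lr_at(mid, cfg), (1e-3 + 1e-5) / 2, tolerance = 1e-12)
  expect_equal(lr_at(mid, cfg), 5.05e-4, tolerance = 1e-12)
  # warm-up is linear
  expect_equal(lr_at(2, cfg), 1e-5 + (1e-3 - 1e-5) * 2 / 5)
  expect_error(lr_at(150, cfg), "outside")
  expect_error(lr_at(-1, cfg), "outside")
  expect_error(mfel_config(epochs = 3, warmup_epochs = 5), "warmup")
  expect_error(mfel_config(lr_final = 1e-2), "lr_final")
})

test_that("a smoke run trains, logs all loss components and predicts", {
  fx <- tiny_samples(n = 4, size = 32, seed = 23)
  cfg <- tiny_config()
  fit <- mfel_fit(fx, cfg, stop_after = 2)
  expect_s3_class(fit, "mfel")
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(c("Lf", "Lb", "Ls", "Lrec", "Lbce", "Ldice", "Lmask",
                    "Ltotal") %in% names(fit$history)))
  # additivity of the logged components
  expect_equal(fit$history$Lrec,
               fit$history$Lf + fit$history$Lb + fit$history$Ls)
  expect_equal(fit$history$Ltotal, fit$history$Lrec + fit$history$Lmask)
  expect_true(all(as.matrix(fit$history[, -(1:2)]) >= 0))
  preds <- predict(fit, fx[1:2])
  expect_length(preds, 2)
  expect_identical(dim(preds[[1]]$prob), c(1L, 32L, 32L))
  expect_true(all(preds[[1]]$mask %in% c(0, 1)))
  expect_identical(dim(preds[[1]]$overlay), c(3L, 32L, 32L))
  expect_error(mfel_fit(list(), cfg), "empty")
})

test_that("fixed seeds reproduce the loss trajectory bitwise", {
  fx <- tiny_samples(n = 4, size = 32, seed = 23)
  cfg <- tiny_config()
  f1 <- mfel_fit(fx, cfg, stop_after = 2)
  f2 <- mfel_fit(fx, cfg, stop_after = 2)
  expect_identical(f1$history, f2$history)
  w1 <- coef(f1); w2 <- coef(f2)
  expect_identical(w1, w2)
  # and evaluation of one fit is deterministic
  e1 <- mfel_evaluate(f1, fx)
  e2 <- mfel_evaluate(f1, fx)
  expect_identical(e1$metrics$mean, e2$metrics$mean)
})

test_that("checkpoint-resume preserves the training trajectory", {
  fx <- tiny_samples(n = 4, size = 32, seed = 23)
  cfg <- tiny_config()
  full <- mfel_fit(fx, cfg)                   # 4 epochs straight through
  part <- mfel_fit(fx, cfg, stop_after = 2)
  ck <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(part, ck)
  resumed <- mfel_fit(fx, resume = ck)
  expect_identical(resumed$epochs_done, full$epochs_done)
  expect_equal(resumed$history, full$history, tolerance = 0)
  expect_identical(coef(resumed), coef(full))
})

test_that("every ablation variant completes a smoke run with coherent gradients", {
  fx <- tiny_samples(n = 2, size = 32, seed = 29)
  for (ab in mfel:::ABLATIONS) {
    cfg <- tiny_config(ablation = ab)
    fit <- mfel_fit(fx, cfg, stop_after = 2)
    expect_identical(nrow(fit$history), 2L)
    expect_true(all(is.finite(fit$history$Ltotal)))
    # every parameter the variant instantiates is reached by backward
    expect_true(all(fit$grad_touched), info = ab)
    nm <- names(model_params <- mfel:::model_params(fit$model))
    if (ab == "no_fiir") {
      # reconstruction losses identically zero, Ltotal == Lmask
      expect_true(all(fit$history$Lrec == 0))
      expect_equal(fit$history$Ltotal, fit$history$Lmask, tolerance = 0)
      # and no reconstruction/fusion parameters exist at all
      expect_false(any(grepl("^(enc_f|enc_b|enc_r|dec_|afm|bfm)", nm)))
    } else {
      expect_true(any(grepl("^enc_r", nm)))
    }
    if (ab == "no_mamba") expect_false(any(grepl("^mamba", nm)))
    if (ab == "afm_summary") expect_false(any(grepl("^afm", nm)))
    if (ab == "afm_concat") expect_true(any(grepl("^afm_cat", nm)))
    if (ab == "bfm_summary") expect_false(any(grepl("^bfm", nm)))
    if (ab == "bfm_concat") expect_true(any(grepl("^bfm_cat", nm)))
  }
})

test_that("the no-mamba variant bypasses the deep block with the identity", {
  cfg <- tiny_config(ablation = "no_mamba")
  m <- tiny_model(cfg)
  s <- tiny_samples(n = 1, size = 32, seed = 31)[[1]]
  expect_null(m$mamba)
  # identical fused pyramid flows straight into the head
  img <- mfel:::ag_const(s$image)
  pyr_s <- mfel:::encoder_forward(m$enc_s, img)
  rec <- mfel:::fiir_forward_ag(m, img, training = FALSE)$calibrated_pyramid
  fused3 <- mfel:::bfm_forward(m$bfm[[3]], pyr_s[[3]], rec[[3]])
  prob <- mfel:::predict_prob(m, s$image)
  expect_identical(dim(prob), c(1L, 32L, 32L))
})

test_that("evaluation matches training-path metrics and handles missing masks", {
  fx <- tiny_samples(n = 3, size = 32, seed = 37)
  cfg <- tiny_config()
  fit <- mfel_fit(fx, cfg, stop_after = 1)
  dir <- withr::local_tempdir()
  ev <- mfel_evaluate(fit, fx, out_dir = dir)
  expect_identical(nrow(ev$metrics$per_image), 3L)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(all(file.exists(file.path(dir, paste0(vapply(fx, `[[`, "", "id"),
                                                    "_pred.png")))))
  # evaluating twice from a reloaded checkpoint is identical
  ck <- file.path(dir, "ck.rds")
  save_checkpoint(fit, ck)
  ev2 <- mfel_evaluate(ck, fx)
  expect_identical(ev$metrics$mean, ev2$metrics$mean)
  # cross-dataset evaluation (different fixture spec) runs fine
  other <- tiny_samples(n = 2, size = 32, seed = 41, hair_artifacts = TRUE)
  evx <- mfel_evaluate(fit, other)
  expect_identical(nrow(evx$metrics$per_image), 2L)
  # unlabeled samples: predictions only, with a warning
  unl <- fx
  unl[[2]]$mask <- NULL
  expect_warning(evu <- mfel_evaluate(fit, unl), "without ground truth")
  expect_identical(nrow(evu$metrics$per_image), 2L)
  expect_length(evu$predictions, 3)
})

test_that("prediction overlays agree with confusion counts", {
  fx <- tiny_samples(n = 1, size = 32, seed = 43)
  fit <- mfel_fit(fx, tiny_config(), stop_after = 1)
  pr <- predict(fit, fx)[[1]]
  cc <- confusion(pr$mask, fx[[1]]$mask)
  fn <- fx[[1]]$mask[1, , ] == 1 & pr$mask[1, , ] == 0
  fp <- pr$mask[1, , ] == 1 & fx[[1]]$mask[1, , ] == 0
  expect_identical(sum(fn), cc$FN)
  expect_identical(sum(fp), cc$FP)
  changed <- apply(abs(pr$overlay - fx[[1]]$image), c(2, 3), sum) > 1e-12
  expect_identical(changed, fn | fp)
})

test_that("print, summary, plot and coef methods behave", {
  fx <- tiny_samples(n = 2, size = 32, seed = 47)
  fit <- mfel_fit(fx, tiny_config(), stop_after = 1)
  expect_output(print(fit), "variant")
  expect_output(print(summary(fit)), "Ltotal")
  expect_s3_class(summary(fit), "summary.mfel")
  w <- coef(fit)
  expect_true(length(w) > 50)
  expect_true(all(vapply(w, is.numeric, TRUE)))
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
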