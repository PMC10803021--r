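# Training engine: optimizer, scheduler, checkpoint retention, and the
# train/evaluate/predict protocol on small in-memory datasets.

test_that("AdamW descends a simple quadratic", {
  params <- list(w = c(5, -3))
  grads_of <- function(p) list(w = 2 * p$w)  # d/dw (w^2)
  st <- es$adamw_init(params)
  cfg <- train_config()
  for (i in 1:200) {
    upd <- es$adamw_step(params, grads_of(params), st, lr = 0.05, cfg)
    params <- upd$params; st <- upd$state
  }
  expect_lt(sum(params$w^2), 1e-2)
})

test_that("checkpoint set keeps the k best scores in order", {
  set.seed(2)
  scores <- runif(40)
  set <- list()
  for (i in seq_along(scores)) {
    set <- checkpoint_insert(set, list(miou = scores[i], epoch = i), k = 5)
    kept <- vapply(set, `[[`, numeric(1), "miou")
    expect_true(!is.unsorted(rev(kept)))          # sorted decreasing
    expect_lte(length(set), 5L)
    # no retained snapshot is worse than any discarded one
    expect_equal(kept, sort(scores[1:i], decreasing = TRUE)[seq_along(kept)])
  }
})

test_that("plateau scheduler only ever decreases the learning rate", {
  st <- es$plateau_init(1e-3, factor = 0.5, patience = 2, min_lr = 1e-5)
  set.seed(3)
  lrs <- numeric(0)
  metric <- cumsum(rnorm(30, sd = 0.1))  # wandering metric
  for (m in metric) {
    st <- es$plateau_update(st, m)
    lrs <- c(lrs, st$lr)
  }
  expect_true(all(diff(lrs) <= 0))
  expect_gte(min(lrs), 1e-5)
  # a long plateau halves the rate after `patience` stale validations
  st <- es$plateau_init(1e-3, 0.5, 2, 1e-6)
  st <- es$plateau_update(st, 0.9)
  for (i in 1:3) st <- es$plateau_update(st, 0.9)  # no improvement
  expect_equal(st$lr, 5e-4)
})

test_that("training is reproducible and the loss decreases", {
  scenes <- in_memory_scenes(4, seed0 = 300, size = 64)
  cfg <- tiny_config()
  tc <- train_config(epochs = 50, batch_size = 2, val_every = 10,
                     max_steps = 20, seed = 5)
  r1 <- train(build_model(cfg, seed = 2), scenes, config = tc)
  r2 <- train(build_model(cfg, seed = 2), scenes, config = tc)
  expect_equal(tail(r1$log$loss, 1), tail(r2$log$loss, 1), tolerance = 1e-12)
  steps1 <- r1$log[is.na(r1$log$val_miou), ]
  expect_lt(mean(tail(steps1$loss, 3)), steps1$loss[1])
  expect_gte(length(r1$checkpoints), 1L)
})

test_that("training aborts on an empty split and caps retained checkpoints", {
  scenes <- in_memory_scenes(3, seed0 = 400, size = 64)
  m <- build_model(tiny_config(), seed = 1)
  sp <- list(train = integer(0), val = 1L)
  expect_error(train(m, scenes, split = sp, config = train_config()), "empty split")
  tc <- train_config(epochs = 8, batch_size = 3, val_every = 1,
                     top_k_checkpoints = 3, seed = 2)
  run <- train(m, scenes, config = tc)
  expect_lte(length(run$checkpoints), 3L)
})

test_that("evaluation averages per-checkpoint metrics arithmetically", {
  scenes <- in_memory_scenes(2, seed0 = 500, size = 64)
  m <- build_model(tiny_config(), seed = 4)
  # stub checkpoints: identical states, hand-set validation scores
  st <- es$model_state(m)
  cks <- lapply(c(0.9, 0.92, 0.94, 0.96, 0.98), function(s) {
    list(state = st, miou = s, epoch = 1L)
  })
  expect_equal(mean(vapply(cks, `[[`, numeric(1), "miou")), 0.94)
  ev <- evaluate(cks, scenes, rows = 1:2, model = m)
  expect_equal(nrow(ev$per_checkpoint), 5L)
  # identical states -> identical metrics; the mean equals each entry
  expect_equal(unname(ev$mean["miou"]), ev$per_checkpoint$miou[1])
  # a single checkpoint's average is itself
  ev1 <- evaluate(cks[1], scenes, rows = 1:2, model = m)
  expect_equal(unname(ev1$mean["miou"]), ev1$per_checkpoint$miou[1])
})

test_that("end-to-end mean test mIoU lies between checkpoint extremes", {
  scenes <- in_memory_scenes(6, seed0 = 600, size = 64)
  sp <- list(train = 1:4, val = 5L, test = 6L)
  m <- build_model(tiny_config(), seed = 6)
  run <- train(m, scenes, split = sp,
               config = train_config(epochs = 6, batch_size = 2, val_every = 2,
                                     top_k_checkpoints = 3, seed = 7))
  ev <- evaluate(run, scenes, rows = sp$test)
  expect_gte(ev$mean["miou"], min(ev$per_checkpoint$miou) - 1e-12)
  expect_lte(ev$mean["miou"], max(ev$per_checkpoint$miou) + 1e-12)
})

test_that("prediction is deterministic and degenerate heads give background", {
  m <- build_model(tiny_config(), seed = 8)
  img <- in_memory_scenes(1, seed0 = 700, size = 64)[[1]]$image
  p1 <- predict_masks(m, img)
  p2 <- predict_masks(m, img)
  expect_identical(p1, p2)
  # zero classifier: all logits equal -> argmax ties break to class 0
  m$params[["head.cls.w"]][] <- 0
  m$params[["head.cls.b"]][] <- 0
  expect_true(all(predict_masks(m, img) == 0L))
})

test_that("a run directory holds config, log and checkpoints", {
  rundir <- withr::local_tempdir()
  scenes <- in_memory_scenes(2, seed0 = 800, size = 64)
  m <- build_model(tiny_config(), seed = 9)
  run <- train(m, scenes, config = train_config(epochs = 2, batch_size = 2,
                                                val_every = 1, seed = 1),
               rundir = rundir)
  expect_true(file.exists(file.path(rundir, "train_config.yaml")))
  expect_true(file.exists(file.path(rundir, "model_config.yaml")))
  expect_true(file.exists(file.path(rundir, "log.csv")))
  expect_gte(length(list.files(rundir, pattern = "^checkpoint_")), 1L)
  # config round-trips through YAML
  cfg2 <- read_model_config(file.path(rundir, "model_config.yaml"))
  expect_equal(unclass(cfg2), unclass(tiny_config()))
})
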