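test_that("egg-level splits are stratified, disjoint and seeded", {
  tab <- simulate_dataset(tiny_sim_config(n_eggs = 10L, scans = 2L))
  sp <- stratified_egg_split(tab, 0.2, seed = 5)
  expect_length(intersect(sp$train_eggs, sp$test_eggs), 0)
  egg_var <- tapply(tab$variety, tab$egg_id, function(v) v[1])
  for (v in unique(tab$variety)) {
    expect_equal(sum(egg_var[sp$test_eggs] == v), 2)  # 20% of 10 eggs
  }
  sp2 <- stratified_egg_split(tab, 0.2, seed = 5)
  expect_identical(sp, sp2)
  # all scans and days of one egg stay on one side
  test_rows <- tab$egg_id %in% sp$test_eggs
  expect_setequal(unique(tab$egg_id[test_rows]), sp$test_eggs)
})

test_that("cross-entropy losses reproduce closed-form values", {
  u <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- c("a", "b", "c", "a")
  expect_equal(task_loss(u, y), log(3))
  perfect <- one_hot(y, c("a", "b", "c"))
  expect_equal(task_loss(pmin(pmax(perfect, 1e-15), 1), y), 0, tolerance = 1e-10)
  # one sample certain, one at 0.5 on the truth
  p <- rbind(c(1, 0, 0), c(0.5, 0.25, 0.25))
  colnames(p) <- c("a", "b", "c")
  expect_equal(task_loss(p, c("a", "a")), log(2) / 2)
  expect_error(task_loss(p * 2, c("a", "a")), "sum")
})

test_that("joint loss is the stated weighted sum", {
  u <- matrix(1 / 3, 5, 3, dimnames = list(NULL, 1:3))
  y <- sample(1:3, 5, replace = TRUE)
  expect_equal(joint_loss(u, y, u, y, loss_weights(0.5, 0.5)), log(3))
  expect_equal(joint_loss(u, y, u, y, loss_weights(0, 0)), 0)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    p1 <- row_norm(matrix(runif(15), 5, 3)); colnames(p1) <- 1:3
    p2 <- row_norm(matrix(runif(15), 5, 3)); colnames(p2) <- 1:3
    expect_equal(joint_loss(p1, y, p2, y, loss_weights(a, b)),
                 a * task_loss(p1, y) + b * task_loss(p2, y))
  }
})

test_that("training reduces loss, restores the best epoch, and anneals the lr", {
  cfg <- tiny_sim_config(n_eggs = 10L, scans = 1L, n_bands = 30L, seed = 3)
  tab <- snv_table(simulate_dataset(cfg))
  bands <- seq(2, 30, length.out = 7)
  net <- build_network(tiny_model_config(), "mt_ctse", seed = 1)
  tc <- train_config(epochs = 40, seed = 42, batch_size = 16,
                     early_stop_patience = 40)
  fitted <- fit_network(net, tab, bands, tc)
  h <- fitted$history
  expect_lt(h$train_loss[fitted$best_epoch], h$train_loss[1])
  expect_lt(h$lr[nrow(h)], h$lr[1])
  expect_equal(h$lr[1], tc$lr * 0.5 * (1 + cos(0)))
  expect_true(all(diff(h$lr) < 0))
  expect_equal(fitted$bands, bands)

  # bit-identical rerun under the same seed
  fitted2 <- fit_network(net, tab, bands, tc)
  expect_identical(fitted$params, fitted2$params)
  expect_identical(fitted$history, fitted2$history)
})

test_that("single-task fit trains only its own head", {
  cfg <- tiny_sim_config(n_eggs = 8L, scans = 1L, n_bands = 30L, seed = 9)
  tab <- snv_table(simulate_dataset(cfg))
  bands <- seq(2, 30, length.out = 7)
  net <- build_network(tiny_model_config(), "st_ctse_task1", seed = 2)
  fitted <- fit_network(net, tab, bands,
                        train_config(epochs = 10, seed = 1, batch_size = 16))
  expect_true(all(is.na(fitted$history$train_acc2)))
  expect_false(anyNA(fitted$history$train_acc1))
})

test_that("cross-validation partitions eggs into the requested folds", {
  cfg <- tiny_sim_config(n_eggs = 10L, scans = 1L, n_bands = 30L, seed = 13)
  tab <- snv_table(simulate_dataset(cfg))
  bands <- seq(2, 30, length.out = 7)
  cv <- cross_validate(tab, bands, tiny_model_config(), "mt_ctse",
                       train_config(epochs = 6, folds = 5, seed = 1,
                                    batch_size = 16))
  expect_length(cv$histories, 5)
  expect_equal(nrow(cv$fold_metrics), 5)
  expect_true(all(cv$summary$metric == c("val_loss", "val_acc1", "val_acc2")))
  m <- cv$fold_metrics$val_acc1
  s <- cv$summary
  expect_gte(s$mean[s$metric == "val_acc1"], min(m))
  expect_lte(s$mean[s$metric == "val_acc1"], max(m))
  expect_equal(s$sd[s$metric == "val_acc1"], sd(m))
})

test_that("no egg crosses a split or fold boundary", {
  cfg <- tiny_sim_config(n_eggs = 10L, scans = 2L, n_bands = 30L, seed = 17)
  tab <- snv_table(simulate_dataset(cfg))
  sp <- stratified_egg_split(tab, 0.2, seed = 3)
  tr <- st_subset(tab, tab$egg_id %in% sp$train_eggs)
  te <- st_subset(tab, tab$egg_id %in% sp$test_eggs)
  expect_length(intersect(unique(tr$egg_id), unique(te$egg_id)), 0)
  expect_equal(nrow(tr$reflectance) + nrow(te$reflectance), nrow(tab$reflectance))
})
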