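test_that("architecture invariants are enforced at construction", {
  arch <- ae_architecture()
  expect_identical(arch$filters,
                   c(64L, 32L, 32L, 32L, 64L, 1L, 1L, 64L, 32L, 32L, 32L,
                     64L, 1L))
  expect_identical(arch$strides,
                   c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 1L))
  expect_error(ae_architecture(filters = rep(32, 12)), "13 layers")
  expect_error(ae_architecture(image_size = 100), "multiple of 32")
})

test_that("layer shape table matches the hand-computed halving/doubling", {
  ae <- build_ae(ae_architecture(image_size = 128), seed = 1)
  expect_identical(ae_layer_sizes(ae),
                   c(64L, 32L, 16L, 8L, 4L, 4L,      # encoder
                     4L, 8L, 16L, 32L, 64L, 128L,    # decoder
                     128L))                          # output layer
  ae64 <- build_ae(ae_architecture(image_size = 64), seed = 1)
  expect_identical(ae_layer_sizes(ae64)[13], 64L)
})

test_that("forward pass maps 128x128x3 to 128x128x3 and is seeded", {
  ae <- build_ae(ae_architecture(image_size = 128), seed = 3)
  set.seed(1)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  out <- reconstruct(ae, img)
  expect_equal(dim(out), c(128, 128, 3))
  expect_true(all(out >= 0 & out <= 1))  # sigmoid output
  ae2 <- build_ae(ae_architecture(image_size = 128), seed = 3)
  expect_identical(reconstruct(ae2, img), out)
  ae3 <- build_ae(ae_architecture(image_size = 128), seed = 4)
  expect_false(identical(reconstruct(ae3, img), out))
})

test_that("reconstruction error follows its closed forms and oracle", {
  ones <- array(1, c(8, 8, 3))
  zeros <- array(0, c(8, 8, 3))
  expect_equal(reconstruction_mse(ones, ones), 0)
  expect_equal(reconstruction_mse(ones, zeros), 1)
  set.seed(2)
  a <- array(runif(8 * 8 * 3), c(8, 8, 3))
  b <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(reconstruction_mse(a, b), oracle_image_mse(a, b),
               tolerance = 1e-12)
  expect_error(reconstruction_mse(a, array(0, c(4, 4, 3))), "differ")
})

test_that("training reduces the loss and is reproducible", {
  set.seed(10)
  imgs <- lapply(1:12, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  ae <- build_ae(ae_architecture(image_size = 32), seed = 2)
  expect_error(ae_mse(ae, imgs[[1]]), "untrained")
  expect_error(train_ae(ae, list()), "empty")

  trained <- train_ae(ae, imgs, epochs = 5, batch_size = 6, seed = 2)
  expect_length(trained$loss_trace, 5)
  expect_lt(trained$loss_trace[5], trained$loss_trace[1])

  again <- train_ae(build_ae(ae_architecture(image_size = 32), seed = 2),
                    imgs, epochs = 5, batch_size = 6, seed = 2)
  expect_identical(trained$loss_trace, again$loss_trace)

  v <- ae_mse(trained, imgs[[1]])
  expect_gte(v, 0)
  expect_equal(v, reconstruction_mse(imgs[[1]], reconstruct(trained, imgs[[1]])))
  # batched and single-image inference agree to single-precision accuracy
  # (the network computes in float; GEMM blocking differs with batch shape)
  expect_equal(ae_mse_batch(trained, imgs[1:3]),
               vapply(imgs[1:3], function(s) ae_mse(trained, s), numeric(1)),
               tolerance = 1e-6)
})

test_that("image dimension mismatches are rejected", {
  ae <- fx_tiny_ae()
  expect_error(reconstruct(ae, array(0, c(64, 64, 3))), "dimensions")
})
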