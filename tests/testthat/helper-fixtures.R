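# Shared fixtures, built lazily once per test run and cached in this
# environment (test files run sequentially in one process).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small default patient + skull
test_patient <- function(seed = 11) sample_population(1, seed = seed)[1, ]

test_skull <- function(resolution = 900, seed = 11) {
  fixture(paste0("skull_", resolution, "_", seed), function() {
    build_skull(test_patient(seed), resolution = resolution)
  })
}

# medium corpus shared by pipeline-level tests: 8 patients x ~22 configs
test_corpus <- function() {
  fixture("corpus_medium", function() {
    run_corpus(n_patients = 8, master_seed = 404, resolution = 1000,
               doe_args = list(count_mean = 22, count_sd = 1.5,
                               count_range = c(18, 26)))
  })
}

test_split <- function() {
  fixture("split_medium", function() {
    split_and_scale(test_corpus()$dataset, 0.33, seed = 7)
  })
}

test_svm_model <- function() {
  fixture("svm_medium", function() {
    train_model(test_split(), "svm",
                list(kernel = "rbf", C = 1.85, epsilon = 0.01, gamma = "auto"),
                seed = 7)
  })
}

# synthetic regression split with known structure, for fast model tests
make_linear_split <- function(n = 120, p = 4, k = 2, noise = 0, seed = 5) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n)
    B <- matrix(stats::rnorm(p * k), p)
    Y <- X %*% B + noise * matrix(stats::rnorm(n * k), n)
  })
  fc <- paste0("x", seq_len(p)); oc <- paste0("b_out_", seq_len(k))
  colnames(X) <- fc; colnames(Y) <- oc
  ntest <- round(0.25 * n)
  structure(list(
    train = tibble::as_tibble(cbind(
      as.data.frame(X[-(1:ntest), , drop = FALSE]),
      as.data.frame(Y[-(1:ntest), , drop = FALSE]))),
    test = tibble::as_tibble(cbind(
      as.data.frame(X[1:ntest, , drop = FALSE]),
      as.data.frame(Y[1:ntest, , drop = FALSE]))),
    scaler = list(center = NULL, scale = NULL, flagged = character()),
    feature_cols = fc, output_cols = oc, test_idx = 1:ntest, seed = seed),
    class = "sac_split")
}

expect_mesh_equal <- function(a, b, tol = 1e-9) {
  testthat::expect_equal(dim(a$vertices), dim(b$vertices))
  testthat::expect_equal(a$faces, b$faces)
  testthat::expect_lt(max(abs(a$vertices - b$vertices)), tol)
}
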