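# shared fixtures: closed-form subset-cost landscapes and small tables

# landscape where any mask containing feature 1 classifies perfectly and
# all others are at chance; global optimum is the singleton {1}
planted_landscape <- function(D, planted = 1L, base = 0.5) {
  force(D); force(planted); force(base)
  function(mask) {
    bits <- if (inherits(mask, "subset_mask")) mask$bits else as.integer(mask)
    if (sum(bits) == 0L) return(wbmfs:::worst_fitness(D))
    acc <- if (all(bits[planted] == 1L)) 1.0 else base
    fitness(acc, sum(bits), D)
  }
}

# constant-cost landscape (no structure at all)
constant_landscape <- function(D, I = 0.3) {
  function(mask) {
    bits <- if (inherits(mask, "subset_mask")) mask$bits else as.integer(mask)
    structure(list(I = I, accuracy = 1 - I, n_selected = sum(bits),
                   n_total = D), class = "fitness_value")
  }
}

# evaluator with per-feature partial credit: accuracy grows with each
# planted feature present, so refinement pressure exists in both directions
additive_landscape <- function(D, planted, gain = 0.2, base = 0.4) {
  force(D); force(planted)
  function(mask) {
    bits <- if (inherits(mask, "subset_mask")) mask$bits else as.integer(mask)
    if (sum(bits) == 0L) return(wbmfs:::worst_fitness(D))
    acc <- min(1, base + gain * sum(bits[planted]))
    fitness(acc, sum(bits), D)
  }
}

random_table <- function(n = 5, d = 7, network = "netX", seed = 42) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * d), n, d), network = network)
}

# tiny two-class table where column 1 separates the classes perfectly and
# the rest is noise
separable_table <- function(n_per_class = 10, d = 6, gap = 10, seed = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * d), n, d)
  y <- factor(rep(c("a", "b"), each = n_per_class))
  x[, 1] <- ifelse(y == "a", -gap, gap) + rnorm(n, sd = 0.1)
  list(table = feature_table(x, network = "sep"), labels = y)
}
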