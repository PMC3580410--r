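# shared fixture builders; everything is generated in code

clique_edges <- function(genes, weight) {
  p <- utils::combn(genes, 2L)
  data.frame(from = p[1L, ], to = p[2L, ], weight = weight,
             provenance = weight, stringsAsFactors = FALSE)
}

# tiny expression dataset with iid normal values and exponential survival
tiny_cohort <- function(n_genes = 10, n_samples = 30, seed = 1,
                        event_prob = 0.7) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_dataset(v, time = rexp(n_samples) + 0.01,
                     event = rbinom(n_samples, 1, event_prob))
}

# eight-subject hand dataset with a binary covariate, mixed censoring
hand_surv <- function() {
  list(x = c(0, 0, 0, 0, 1, 1, 1, 1),
       time = c(2, 4, 5, 7, 1, 3, 6, 8),
       event = c(1, 1, 0, 1, 1, 1, 1, 0))
}

# longhand Breslow partial log-likelihood for a single covariate
breslow_loglik_longhand <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    for (i in which(time == t & event == 1)) {
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}
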