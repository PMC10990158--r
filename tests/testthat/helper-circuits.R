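# Small circuits used across tests.

and2_table <- function() {
  truth_table(boolean_circuit(2, list(list(op = "AND", args = c(1, 2)))))
}

xor2_table <- function() {
  truth_table(boolean_circuit(2, list(list(op = "XOR", args = c(1, 2)))))
}

or2_table <- function() {
  truth_table(boolean_circuit(2, list(list(op = "OR", args = c(1, 2)))))
}

# a table channel with explicit means/scales for the two binary values
make_binary_channel <- function(means, scales, feature = "x") {
  d <- length(means[[1]])
  ch <- encoder_table(feature, levels = c(0, 1), latent_dim = d)
  pre <- function(s) log(expm1(pmax(s - 1e-6, 1e-12))) - log(exp(1) - 1)
  ch$params$P <- rbind(c(means[[1]], pre(scales[[1]])),
                      c(means[[2]], pre(scales[[2]])))
  ch
}

uniform_binary_pmf <- function() data.frame(value = c(0, 1), prob = c(0.5, 0.5))
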