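# Shared fixtures, all generated in code.

nt <- coev_alphabet("nucleotide")
aa <- coev_alphabet("aa")
ab2 <- coev_alphabet(c("A", "B"))

# small fixed 4-leaf tree used across modules
toy_tree <- function() {
  parse_newick("((a:0.1,b:0.2):0.3,(c:0.1,d:0.4):0.2);")
}

# a pair_column_data object from a named token vector
toy_pair_data <- function(tokens, alphabet = nt) {
  structure(list(states = tokens, pos1 = 1, pos2 = 2, alphabet = alphabet),
            class = "pair_column_data")
}

# random parameters, tree and data for property-style suites
random_instance <- function(n_leaves = sample(2:5, 1), alphabet = nt) {
  tr <- random_tree(n_leaves, mean_bl = 0.4)
  params <- coev_params(runif(1, 0.1, 5), runif(1, 0.1, 5),
                        runif(1, 0.1, 5), runif(1, 0.1, 5))
  profile <- random_profile(alphabet)
  Q <- build_coev_Q(params, profile, alphabet)
  tokens <- sample(rownames(Q), n_leaves, replace = TRUE)
  names(tokens) <- tr$tip.label
  list(tree = tr, params = params, profile = profile, Q = Q,
       data = toy_pair_data(tokens, alphabet))
}
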