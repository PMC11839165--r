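# Small model-free networks used across the engine tests.

pure_death_network <- function(n0 = 100L, d = 0.01) {
  reaction_network(
    species = "n",
    initial_state = c(n = n0),
    reactions = list(
      reaction("death", c(n = -1), rate_spec(d, affine("n")))),
    meta = list(params = list(d = d)))
}

birth_death_network <- function(n0 = 0L, b = 5, d = 0.1) {
  reaction_network(
    species = "n",
    initial_state = c(n = n0),
    reactions = list(
      reaction("birth", c(n = +1), rate_spec(b, affine(const = 1))),
      reaction("death", c(n = -1), rate_spec(d, affine("n")))))
}

isomerization_network <- function(n = 50L, k12 = 1, k21 = 1) {
  reaction_network(
    species = c("A", "B"),
    initial_state = c(A = n, B = 0),
    reactions = list(
      reaction("fwd", c(A = -1, B = +1), rate_spec(k12, affine("A"))),
      reaction("rev", c(A = +1, B = -1), rate_spec(k21, affine("B")))),
    conserved = list(list(coef = c(A = 1, B = 1), total = n)))
}

# the same death process written with an R-function propensity, to exercise
# the reference engine
pure_death_network_r <- function(n0 = 100L, d = 0.01) {
  reaction_network(
    species = "n",
    initial_state = c(n = n0),
    reactions = list(
      reaction("death", c(n = -1),
               propensity = function(state, t) d * state[["n"]])))
}

final_state_of <- function(traj) {
  as.data.frame(traj)[nrow(traj$states), , drop = FALSE]
}

# readout of the V1/V2 pair at (or nearest to) a given time
pair_at <- function(traj, t_read) {
  df <- as.data.frame(traj)
  df[which.min(abs(df$time - t_read)), c("V1", "V2")]
}
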