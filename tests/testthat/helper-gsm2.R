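# Shared fixtures: the reference kinetic parameters (r = 4, a = 0.1,
# b_tilde = 0.01) at two problem sizes, built in code at test time.

ref_rates <- function(K = 100) kinetic_rates(r = 4, a = 0.1, b_tilde = 0.01, K = K)

small_rates <- function() ref_rates(K = 20)

# Closed-form law of the linear network (b = 0): starting from x0 sublethal
# lesions, each one independently is still present at time t with
# probability exp(-(a+r)t), has died lethally with probability p_lethal(t),
# or was repaired. Used as an independent oracle.
linear_race <- function(rates, t) {
  ar <- rates$a + rates$r
  surv <- exp(-ar * t)
  p_lethal <- rates$a / ar * (1 - surv)
  list(surv = surv, p_lethal = p_lethal)
}
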