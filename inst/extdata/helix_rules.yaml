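# Declarative alpha-helix rule set (version 1).
#
# A scan bracket (opened at a hydrophilic residue, closed at the next
# hydrophilic residue within six neighbours) is classified helix when ANY case
# whose `n` list contains the bracket's intervening-residue count has at least
# one alternative whose conditions ALL hold.
#
# Condition fields, evaluated on the intervening residues only:
#   sum_q      sum of fractional charges (elementary charges)
#   abs_sum_q  |sum_q|
#   prod_q     product of fractional charges
#   sum_h      sum of hydropathy values (scale units)
#   q          the per-residue charge vector (needs `index` or `quantifier`)
#   abs_q      |q| per residue (needs `quantifier`)
# Ops: gt, lt, eq, between (strict on both ends), neq_pair (q[i] != q[j]).
#
# The printed source table lists cases only for n = 1, 3, 5; even bracket
# widths are handled by the nearest smaller case (n = 2 -> 1, 4 -> 3, 6 -> 5).
# One printed alternative for n = 1 ("1 < a < 0.5" with a negative product) is
# self-contradictory; it is kept here literally and can never fire.
version: 1
cases:
  - "n": [1, 2]
    alternatives:
      - conditions:
          - {field: sum_q, op: between, lo: 0.0, hi: 0.2}
          - {field: prod_q, op: gt, value: 0.0}
      - conditions:
          - {field: sum_q, op: lt, value: -0.5}
          - {field: prod_q, op: eq, value: 0.0}
      - conditions:
          - {field: q, index: 1, op: gt, value: 0.9}
          - {field: sum_h, op: lt, value: -0.3}
      - conditions:
          - {field: sum_q, op: between, lo: 1.0, hi: 0.5}
          - {field: prod_q, op: lt, value: 0.0}
  - "n": [3, 4]
    alternatives:
      - conditions:
          - {field: sum_q, op: gt, value: 1.0}
          - {field: q, op: neq_pair, indices: [2, 3]}
      - conditions:
          - {field: abs_sum_q, op: lt, value: 0.5}
          - {field: sum_h, op: lt, value: -6.0}
  - "n": [5, 6]
    alternatives:
      - conditions:
          - {field: sum_q, op: between, lo: 0.3, hi: 0.5}
      - conditions:
          - {field: abs_sum_q, op: gt, value: 1.0}
      - conditions:
          - {field: q, quantifier: all, op: gt, value: 0.0}
      - conditions:
          - {field: abs_q, quantifier: all, op: gt, value: 0.6}
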