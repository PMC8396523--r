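# Built-in modification deltas (signed elemental-composition grammar).
# hexose and glycation are isobaric on purpose: one Hex residue, two names.
lysine: C6H12N2O
hexose: C6H10O5
glycation: C6H10O5
deamidation: H-1N-1O
pyroglu: H-3N-1
water: H2O
trunc_qivls: C-25H-44N-6O-7
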