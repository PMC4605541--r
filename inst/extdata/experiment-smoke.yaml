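# Small end-to-end smoke experiment: 10 neurons, 100 s of 10 ms bins,
# half the population observed per bin under random-block scanning.
"N": 10
nBins: 10000
pObs: 0.5
scheme: random_blocks
seed: 7
binWidth: 0.01
matchSparsity: true
lambda: 0.0
gradMode: adjusted
network:
  pConn: 0.2
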