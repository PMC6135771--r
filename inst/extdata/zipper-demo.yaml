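# Small packaged demo: replica exchange on the GB1p-like zipper preset
# (reduced units), analysed over the last 60% of sweeps.
model:
  kind: zipper
  preset: GB1p-like
ladder:
  tMin: 1.0
  tMax: 2.5
  nReplicas: 8
run:
  nSweeps: 20000
  exchangeInterval: 10
  productionFraction: 0.6
  seed: 1
  kB: 1
output:
  dir: zipper-demo-out
analysis:
  foldedMin: 4
  unfoldedMax: 1
  unfoldedFloor: 10
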