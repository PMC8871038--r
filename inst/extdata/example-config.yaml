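# Example run configuration for the needlewave CLI:
#   needlewave run --config example-config.yaml --out results/
scenario: cylinder_steel
preset: ci
depth_mm: 6
diameter_mm: 1.5
snapshot_every_us: 3
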