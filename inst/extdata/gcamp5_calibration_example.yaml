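# EXAMPLE calibration constants (GCaMP5-family range) for demonstrations
# and tests only. Scientific use requires the published constants of the
# actual indicator under the actual imaging conditions.
kd: 460            # nM
n_hill: 2.5
dynamic_range: 32.7
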