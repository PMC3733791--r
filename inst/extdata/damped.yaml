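# Damped negative-feedback loop (Hill exponent below the oscillation
# threshold); negative control for steady-state discard logic.
name: damped-goodwin
registry: damped
hill: 2
period_hint: 24
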