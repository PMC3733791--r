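# Built-in Goodwin-type negative-feedback oscillator (~24 h period).
name: goodwin-circadian
registry: goodwin
hill: 10
params: {a: 0.95, b: 0.16, c: 0.32, d: 0.16, e: 0.32, g: 0.16}
period_hint: 24
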