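# adverse-reaction phrases; optional second column: known | candidate
fatigue	known
headache	known
dizziness	known
nausea	known
weight gain	candidate
hair loss	candidate
rash	candidate
fever	candidate
insomnia	candidate
dry mouth	candidate
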