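# 50 common drug keywords (one canonical name per line)
adderall
xanax
seroquel
trazodone
aspirin
prozac
zoloft
lexapro
cymbalta
effexor
wellbutrin
paxil
celexa
abilify
risperdal
zyprexa
lamictal
depakote
lithium
klonopin
ativan
valium
ambien
lunesta
oxycontin
percocet
vicodin
tramadol
codeine
morphine
methadone
suboxone
ritalin
concerta
vyvanse
strattera
lipitor
crestor
zocor
metformin
insulin
lantus
synthroid
nexium
prilosec
zantac
lisinopril
metoprolol
amlodipine
gabapentin
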