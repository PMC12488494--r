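raw_term	doe
agonist	activator
partial agonist	activator
full agonist	activator
activator	activator
positive allosteric modulator	activator
positive modulator	activator
stimulator	activator
inducer	activator
opener	activator
channel opener	activator
releasing agent	activator
antagonist	inhibitor
inhibitor	inhibitor
blocker	inhibitor
channel blocker	inhibitor
negative allosteric modulator	inhibitor
negative modulator	inhibitor
inverse agonist	inhibitor
antisense oligonucleotide	inhibitor
degrader	inhibitor
suppressor	inhibitor
disrupting agent	inhibitor
binding agent	other
mixed agonist/antagonist	other
partial agonist/antagonist	other
modulator	other
allosteric modulator	other
substrate	other
chelator	other
cross-linking agent	other
replacement therapy	other
gene replacement	other
protein replacement	other
cofactor	other
vaccine antigen	other
other	other
unknown	other
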