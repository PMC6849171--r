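term	score
pain	-0.6
ache	-0.5
stiffness	-0.4
swelling	-0.4
discomfort	-0.5
unbearable	-0.9
terrible	-0.9
awful	-0.9
horrible	-0.9
dreadful	-0.9
miserable	-0.8
severe	-0.7
excruciating	-1.0
agonising	-1.0
agonizing	-1.0
bad	-0.6
worse	-0.7
scream	-0.8
cry	-0.7
regret	-0.6
struggle	-0.6
unable	-0.7
difficult	-0.5
hard	-0.4
worried	-0.6
anxious	-0.6
nervous	-0.5
unsure	-0.4
hurt	-0.6
uncomfortable	-0.5
limp	-0.4
problem	-0.4
trouble	-0.4
weak	-0.4
unstable	-0.5
wobbly	-0.4
sore	-0.5
stiff	-0.4
swollen	-0.4
unhappy	-0.7
limited	-0.4
restricted	-0.4
constant	-0.5
sharp	-0.5
stabbing	-0.6
throbbing	-0.5
burning	-0.5
great	0.8
good	0.6
fine	0.5
better	0.7
improve	0.7
confident	0.6
happy	0.7
pleased	0.7
grateful	0.7
comfortable	0.5
able	0.4
easy	0.4
easier	0.5
normal	0.3
manage	0.4
help	0.5
well	0.5
stable	0.4
steady	0.3
strong	0.4
progress	0.5
pain-free	0.8
recover	0.6
settle	0.3
tolerable	0.3
manageable	0.4
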