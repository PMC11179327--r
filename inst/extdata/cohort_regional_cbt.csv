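band,sector,group,mean,ci_lo,ci_hi
total,medial,oa_male,17.9,16.7,19.1
total,medial,oa_female,17.5,16.8,18.1
total,medial,healthy_male,17.1,16.4,17.7
total,medial,healthy_female,17.4,16.6,18.2
total,lateral,oa_male,16.6,15.8,17.4
total,lateral,oa_female,16.9,16.3,17.6
total,lateral,healthy_male,17.3,16.6,18.0
total,lateral,healthy_female,18.1,17.5,18.7
total,anterior,oa_male,23.5,21.8,25.1
total,anterior,oa_female,21.6,20.3,22.8
total,anterior,healthy_male,23.9,22.7,25.1
total,anterior,healthy_female,23.5,22.5,24.5
total,posterior,oa_male,15.6,14.9,16.2
total,posterior,oa_female,15.0,14.5,15.5
total,posterior,healthy_male,16.1,15.6,16.5
total,posterior,healthy_female,16.0,15.5,16.5
most proximal,medial,oa_male,17.3,16.3,18.2
most proximal,medial,oa_female,17.6,16.9,18.3
most proximal,medial,healthy_male,16.8,15.8,17.7
most proximal,medial,healthy_female,17.1,16.3,17.9
most proximal,lateral,oa_male,14.9,14.2,15.6
most proximal,lateral,oa_female,15.9,15.3,16.6
most proximal,lateral,healthy_male,16.8,16.1,17.5
most proximal,lateral,healthy_female,17.6,16.9,18.4
most proximal,anterior,oa_male,20.4,18.9,21.9
most proximal,anterior,oa_female,20.6,19.1,22.0
most proximal,anterior,healthy_male,22.7,21.2,24.3
most proximal,anterior,healthy_female,23.5,22.4,24.6
most proximal,posterior,oa_male,14.6,14.1,15.1
most proximal,posterior,oa_female,15.5,14.8,16.2
most proximal,posterior,healthy_male,15.6,15.1,16.1
most proximal,posterior,healthy_female,16.7,15.7,17.6
proximal,medial,oa_male,16.8,15.6,18.0
proximal,medial,oa_female,17.8,16.9,18.6
proximal,medial,healthy_male,17.1,16.3,18.0
proximal,medial,healthy_female,16.8,15.6,17.9
proximal,lateral,oa_male,16.0,15.0,16.9
proximal,lateral,oa_female,16.4,15.7,17.0
proximal,lateral,healthy_male,17.1,16.3,18.0
proximal,lateral,healthy_female,18.2,17.3,19.1
proximal,anterior,oa_male,21.5,19.7,23.2
proximal,anterior,oa_female,19.9,18.8,21.1
proximal,anterior,healthy_male,21.9,20.9,22.9
proximal,anterior,healthy_female,22.2,21.0,23.4
proximal,posterior,oa_male,15.3,14.7,16.0
proximal,posterior,oa_female,15.4,14.7,16.0
proximal,posterior,healthy_male,16.3,15.6,16.9
proximal,posterior,healthy_female,16.1,15.4,16.9
central proximal,medial,oa_male,16.8,15.5,18.1
central proximal,medial,oa_female,17.2,16.4,18.0
central proximal,medial,healthy_male,16.4,15.3,17.5
central proximal,medial,healthy_female,17.6,16.6,18.6
central proximal,lateral,oa_male,16.1,15.2,16.9
central proximal,lateral,oa_female,17.0,16.3,17.8
central proximal,lateral,healthy_male,17.2,15.9,18.5
central proximal,lateral,healthy_female,18.2,17.2,19.2
central proximal,anterior,oa_male,24.2,22.2,26.2
central proximal,anterior,oa_female,21.4,19.9,22.8
central proximal,anterior,healthy_male,24.0,22.7,25.3
central proximal,anterior,healthy_female,24.1,22.9,25.3
central proximal,posterior,oa_male,15.7,14.8,16.6
central proximal,posterior,oa_female,15.2,14.6,15.9
central proximal,posterior,healthy_male,15.8,15.2,16.4
central proximal,posterior,healthy_female,15.5,15.0,16.0
central distal,medial,oa_male,19.1,17.4,20.7
central distal,medial,oa_female,17.5,16.5,18.4
central distal,medial,healthy_male,17.4,16.2,18.6
central distal,medial,healthy_female,17.4,15.8,18.9
central distal,lateral,oa_male,17.1,16.1,18.0
central distal,lateral,oa_female,17.7,16.9,18.6
central distal,lateral,healthy_male,17.5,16.6,18.4
central distal,lateral,healthy_female,18.4,17.3,19.5
central distal,anterior,oa_male,26.4,24.3,28.5
central distal,anterior,oa_female,23.2,21.5,25.0
central distal,anterior,healthy_male,27.0,25.2,28.9
central distal,anterior,healthy_female,24.4,23.2,25.7
central distal,posterior,oa_male,15.9,15.0,16.8
central distal,posterior,oa_female,14.5,14.0,15.0
central distal,posterior,healthy_male,16.2,15.5,16.9
central distal,posterior,healthy_female,15.4,14.8,16.1
distal,medial,oa_male,20.1,18.1,22.1
distal,medial,oa_female,17.7,16.7,18.6
distal,medial,healthy_male,18.1,16.9,19.3
distal,medial,healthy_female,17.2,15.8,18.7
distal,lateral,oa_male,18.3,17.1,19.5
distal,lateral,oa_female,17.6,16.5,18.6
distal,lateral,healthy_male,18.0,17.2,18.7
distal,lateral,healthy_female,18.7,18.0,19.4
distal,anterior,oa_male,26.6,24.5,28.8
distal,anterior,oa_female,23.9,22.3,25.5
distal,anterior,healthy_male,27.5,25.6,29.4
distal,anterior,healthy_female,24.6,23.1,26.1
distal,posterior,oa_male,16.7,15.8,17.5
distal,posterior,oa_female,14.5,14.0,15.1
distal,posterior,healthy_male,16.6,15.9,17.3
distal,posterior,healthy_female,15.5,15.0,16.0
most distal,medial,oa_male,19.3,16.7,21.8
most distal,medial,oa_female,16.9,16.0,17.8
most distal,medial,healthy_male,17.5,16.3,18.8
most distal,medial,healthy_female,18.9,17.3,20.4
most distal,lateral,oa_male,19.4,17.8,20.9
most distal,lateral,oa_female,17.4,16.5,18.3
most distal,lateral,healthy_male,18.9,17.7,20.0
most distal,lateral,healthy_female,19.0,18.1,19.9
most distal,anterior,oa_male,25.1,23.0,27.3
most distal,anterior,oa_female,22.6,21.4,23.7
most distal,anterior,healthy_male,26.2,24.3,28.1
most distal,anterior,healthy_female,24.5,22.9,26.1
most distal,posterior,oa_male,16.1,15.2,17.0
most distal,posterior,oa_female,14.4,13.8,15.0
most distal,posterior,healthy_male,16.9,16.2,17.5
most distal,posterior,healthy_female,15.5,14.9,16.1
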