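sex,age_group,quintile,p_2004,p_2015
female,<15,1,15.7,11.2
female,<15,2,20.0,15.4
female,<15,3,20.5,20.8
female,<15,4,25.2,23.0
female,<15,5,18.6,29.7
female,15-34,1,21.8,18.8
female,15-34,2,24.0,18.4
female,15-34,3,19.6,20.1
female,15-34,4,19.8,19.2
female,15-34,5,14.9,23.4
female,35-54,1,14.5,13.9
female,35-54,2,18.5,15.9
female,35-54,3,20.9,17.4
female,35-54,4,22.3,22.2
female,35-54,5,23.7,30.6
female,55-64,1,12.5,14.8
female,55-64,2,15.4,12.2
female,55-64,3,17.8,17.4
female,55-64,4,21.7,25.2
female,55-64,5,32.6,30.4
female,65-74,1,11.0,11.2
female,65-74,2,17.3,14.9
female,65-74,3,19.4,16.6
female,65-74,4,22.7,22.5
female,65-74,5,29.6,34.8
female,75+,1,7.7,12.3
female,75+,2,15.3,14.5
female,75+,3,20.4,20.6
female,75+,4,27.3,18.7
female,75+,5,29.3,33.9
male,<15,1,18.8,12.4
male,<15,2,18.6,18.2
male,<15,3,20.3,18.4
male,<15,4,21.9,22.8
male,<15,5,20.3,28.1
male,15-34,1,34.9,29.9
male,15-34,2,26.8,19.5
male,15-34,3,19.4,24.5
male,15-34,4,13.5,14.6
male,15-34,5,5.4,11.5
male,35-54,1,26.1,22.8
male,35-54,2,27.1,20.7
male,35-54,3,20.5,21.7
male,35-54,4,17.1,16.1
male,35-54,5,9.2,18.6
male,55-64,1,19.7,18.0
male,55-64,2,24.0,18.6
male,55-64,3,18.0,20.0
male,55-64,4,20.7,19.8
male,55-64,5,17.6,23.6
male,65-74,1,18.2,18.4
male,65-74,2,17.3,16.8
male,65-74,3,19.8,28.6
male,65-74,4,23.9,19.8
male,65-74,5,20.8,16.4
male,75+,1,15.0,15.9
male,75+,2,17.7,16.4
male,75+,3,20.7,20.9
male,75+,4,23.0,23.2
male,75+,5,16.5,23.7
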