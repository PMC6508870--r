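specimen,joint,parameter,value
Initialised,C2C3,k_y,1.1e6
Initialised,C3C4,k_y,1.1e6
Initialised,C4C5,k_y,1.1e6
Initialised,C5C6,k_y,1.1e6
Initialised,C2C3,b_y,1.0e3
Initialised,C3C4,b_y,1.0e3
Initialised,C4C5,b_y,1.0e3
Initialised,C5C6,b_y,1.0e3
Initialised,C2C3,k_x,63.0e3
Initialised,C3C4,k_x,63.0e3
Initialised,C4C5,k_x,63.0e3
Initialised,C5C6,k_x,63.0e3
Initialised,C2C3,b_x,1.0e3
Initialised,C3C4,b_x,1.0e3
Initialised,C4C5,b_x,1.0e3
Initialised,C5C6,b_x,1.0e3
S1,C2C3,k_y,22.2e6
S1,C3C4,k_y,25.0e6
S1,C4C5,k_y,15.2e6
S1,C5C6,k_y,2.7e6
S1,C2C3,b_y,3.1e3
S1,C3C4,b_y,6.1e3
S1,C4C5,b_y,2.0e3
S1,C5C6,b_y,2.2e3
S1,C2C3,k_x,28.4e3
S1,C3C4,k_x,69.0e3
S1,C4C5,k_x,53.3e3
S1,C5C6,k_x,75.3e3
S1,C2C3,b_x,0.5e3
S1,C3C4,b_x,1.5e3
S1,C4C5,b_x,1.4e3
S1,C5C6,b_x,1.4e3
S2,C2C3,k_y,29.4e6
S2,C3C4,k_y,19.7e6
S2,C4C5,k_y,24.4e6
S2,C5C6,k_y,2.2e6
S2,C2C3,b_y,1.8e3
S2,C3C4,b_y,5.5e3
S2,C4C5,b_y,2.2e3
S2,C5C6,b_y,1.8e3
S2,C2C3,k_x,80.6e3
S2,C3C4,k_x,76.4e3
S2,C4C5,k_x,75.5e3
S2,C5C6,k_x,77.8e3
S2,C2C3,b_x,1.3e3
S2,C3C4,b_x,1.3e3
S2,C4C5,b_x,1.4e3
S2,C5C6,b_x,1.1e3
S3,C2C3,k_y,25.2e6
S3,C3C4,k_y,38.2e6
S3,C4C5,k_y,19.9e6
S3,C5C6,k_y,1.2e6
S3,C2C3,b_y,3.9e3
S3,C3C4,b_y,7.3e3
S3,C4C5,b_y,3.6e3
S3,C5C6,b_y,4.0e3
S3,C2C3,k_x,5.5e3
S3,C3C4,k_x,96.1e3
S3,C4C5,k_x,38.5e3
S3,C5C6,k_x,92.0e3
S3,C2C3,b_x,0.5e3
S3,C3C4,b_x,0.8e3
S3,C4C5,b_x,1.4e3
S3,C5C6,b_x,1.5e3
S4,C2C3,k_y,26.0e6
S4,C3C4,k_y,26.3e6
S4,C4C5,k_y,33.3e6
S4,C5C6,k_y,2.7e6
S4,C2C3,b_y,5.7e3
S4,C3C4,b_y,3.0e3
S4,C4C5,b_y,2.4e3
S4,C5C6,b_y,2.6e3
S4,C2C3,k_x,89.7e3
S4,C3C4,k_x,61.3e3
S4,C4C5,k_x,78.6e3
S4,C5C6,k_x,93.5e3
S4,C2C3,b_x,0.7e3
S4,C3C4,b_x,1.5e3
S4,C4C5,b_x,0.9e3
S4,C5C6,b_x,1.5e3
S5,C2C3,k_y,22.2e6
S5,C3C4,k_y,35.2e6
S5,C4C5,k_y,14.4e6
S5,C5C6,k_y,1.7e6
S5,C2C3,b_y,1.4e3
S5,C3C4,b_y,8.9e3
S5,C4C5,b_y,7.7e3
S5,C5C6,b_y,3.0e3
S5,C2C3,k_x,14.5e3
S5,C3C4,k_x,88.0e3
S5,C4C5,k_x,84.5e3
S5,C5C6,k_x,91.2e3
S5,C2C3,b_x,0.6e3
S5,C3C4,b_x,1.4e3
S5,C4C5,b_x,1.4e3
S5,C5C6,b_x,1.5e3
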