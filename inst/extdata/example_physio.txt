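# Fictive task-control network (9 Boolean nodes).
# Two inputs (the do instruction and the factory) are self-equations; the
# factory supplies energy, the task consumes it, and a locker must stop the
# task whenever energy is missing.
do = do
factory = factory
energy = factory | (energy & !task)
locker = !energy
releaser = do
sequester = !releaser
activator = do & !locker
effector = activator & !sequester
task = effector
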