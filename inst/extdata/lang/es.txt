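El tren de la mañana salió de la estación con unos minutos de retraso, y
los pasajeros miraban los campos pasar detrás de las ventanas mientras la
luz cambiaba lentamente. Se dice a menudo que la mejor manera de conocer
una ciudad es recorrer sus calles temprano, cuando las tiendas todavía
están cerradas y los panaderos son los únicos que trabajan. Hubo un tiempo
en que cada pueblo tenía su propio mercado, y la gente venía de las granjas
cercanas con lo que había cultivado o fabricado durante la semana. El
tiempo puede cambiar muy rápido en esta región, y se aconseja a los
viajeros llevar un abrigo incluso en los meses de verano. Ella escribía
cartas a sus amigas cada domingo por la noche, contando las pequeñas cosas
de la semana y preguntando por sus familias. La biblioteca de la esquina
lleva abierta más de cien años, y la sala de lectura todavía huele a papel
viejo y madera encerada. Cuando por fin se terminó el puente, las dos
mitades de la ciudad crecieron juntas, y una generación después nadie
recordaba cómo era la vida antes. La mayoría de la gente piensa que una
buena comida compartida con amigos sigue siendo uno de los placeres más
sencillos de la vida diaria.
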